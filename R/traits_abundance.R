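#' Construct and validate a trait table
#'
#' Per-taxon native status, growth form and main habitat. Family-rank taxa
#' are never trait-annotated (they are excluded from trait summaries), so
#' `rank` must be species, genus or tribe.
#'
#' @param df data.frame with columns `taxon`, `rank`, `status`, `form`,
#'   `habitat`.
#' @return validated data.frame of class `trait_table`.
#' @export
trait_table <- function(df) {
  req <- c("taxon", "rank", "status", "form", "habitat")
  if (!all(req %in% names(df)))
    stop_hf("trait table needs columns: ", paste(req, collapse = ", "))
  df <- as.data.frame(df)[req]
  lv <- list(rank = c("species", "genus", "tribe"),
             status = c("native_or_near_native", "naturalized", "horticultural"),
             form = c("tree", "shrub", "herb"),
             habitat = c("broadleaved_woodland", "grassland",
                         "hedgerow_linear", "garden"))
  for (col in names(lv)) {
    bad <- !df[[col]] %in% lv[[col]]
    if (any(bad)) stop_hf("invalid ", col, " value(s): ",
                          paste(unique(df[[col]][bad]), collapse = ", "))
  }
  if (anyDuplicated(df$taxon)) stop_hf("duplicate taxa in trait table")
  class(df) <- c("trait_table", "data.frame")
  df
}

#' @rdname trait_table
#' @param path trait TSV path.
#' @export
read_traits_tsv <- function(path) {
  trait_table(data.table::fread(path, sep = "\t", data.table = FALSE))
}

#' Monthly relative read abundance
#'
#' For each (year, month), pools read counts across that month's samples and
#' divides by the month's total assigned reads (the default), or averages
#' per-sample proportions (`method = "mean"`). Months with zero assigned
#' reads are omitted with a warning.
#'
#' @param trt a `taxon_read_table` from [aggregate_reads()].
#' @param metadata data.frame with `sample_id`, `year`, `month` covering
#'   every sample of the table.
#' @param method `"pooled"` (default) or `"mean"`.
#' @return data.frame: `year`, `month`, `taxon`, `rank`, `rra`, `category`
#'   (see [categorize_rra()]). Per month, `rra` sums to 1.
#' @export
monthly_rra <- function(trt, metadata, method = c("pooled", "mean")) {
  method <- match.arg(method)
  ids <- rownames(trt$counts)
  if (!all(ids %in% metadata$sample_id))
    stop_hf("metadata missing samples: ",
            paste(setdiff(ids, metadata$sample_id), collapse = ", "))
  md <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  mo <- unique(md[c("year", "month")])
  mo <- mo[order(order_ym(mo$year, mo$month)), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(mo))) {
    sel <- md$year == mo$year[i] & md$month == mo$month[i]
    sub <- trt$counts[sel, , drop = FALSE]
    if (sum(sub) == 0) {
      warning("month ", mo$year[i], "-", mo$month[i],
              " has zero assigned reads; omitted")
      next
    }
    rra <- if (method == "pooled") colSums(sub) / sum(sub) else {
      p <- sub[rowSums(sub) > 0, , drop = FALSE]
      colMeans(p / rowSums(p))
    }
    out[[length(out) + 1L]] <- data.frame(
      year = mo$year[i], month = mo$month[i],
      taxon = colnames(trt$counts), rank = trt$taxa$rank,
      rra = unname(rra), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out$category <- categorize_rra(out$rra)
  out
}

#' Band a relative read abundance into a forage category
#'
#' Major: rra > 10%; secondary: 1% < rra <= 10%; minor: 0.01% < rra <= 1%;
#' occasional: 0 < rra <= 0.01%; absent: rra = 0. The only strict bound
#' stated for the banding is "over 10%", so the remaining boundaries are
#' half-open intervals closed above (exactly 10% is secondary, exactly
#' 0.01% is occasional).
#'
#' @param rra numeric vector of fractions in [0, 1].
#' @return ordered factor with levels
#'   absent < occasional < minor < secondary < major.
#' @export
categorize_rra <- function(rra) {
  if (any(rra < 0 | rra > 1 | is.na(rra)))
    stop_hf("rra values must lie in [0, 1]")
  lv <- c("absent", "occasional", "minor", "secondary", "major")
  idx <- ifelse(rra > 0.10, 5L,
         ifelse(rra > 0.01, 4L,
         ifelse(rra > 1e-4, 3L,
         ifelse(rra > 0, 2L, 1L))))
  factor(lv[idx], levels = lv, ordered = TRUE)
}

#' Proportion of reads and taxon richness by plant trait
#'
#' For one trait dimension (status, form or habitat): the fraction of reads
#' per category level, per month and overall, together with the number of
#' distinct taxa per level. Family-rank taxa carry no traits and are
#' excluded before computation; the remaining proportions are renormalized
#' over categorized reads and the excluded read mass is logged in the
#' `"excluded_reads"` attribute. A missing trait record for any non-family
#' taxon is an error.
#'
#' @param trt a `taxon_read_table`.
#' @param traits a [trait_table()].
#' @param dimension one of `"status"`, `"form"`, `"habitat"`.
#' @param metadata optional `sample_id`/`year`/`month` data.frame; when
#'   supplied, per-month rows are included alongside the overall rows.
#' @return data.frame: `period` (`"overall"` or `"YYYY-MM"`), `level`,
#'   `prop_reads`, `n_taxa`.
#' @export
trait_proportions <- function(trt, traits, dimension = c("status", "form",
                                                         "habitat"),
                              metadata = NULL) {
  dimension <- match.arg(dimension)
  fam <- trt$taxa$rank == "family"
  need <- trt$taxa$taxon[!fam]
  missing <- setdiff(need, traits$taxon)
  if (length(missing))
    stop_hf("no trait record for non-family taxa: ",
            paste(missing, collapse = ", "))
  counts <- trt$counts[, !fam, drop = FALSE]
  lev <- traits[[dimension]][match(colnames(counts), traits$taxon)]
  levels_all <- levels(factor(traits[[dimension]],
    levels = switch(dimension,
      status = c("native_or_near_native", "naturalized", "horticultural"),
      form = c("tree", "shrub", "herb"),
      habitat = c("broadleaved_woodland", "grassland", "hedgerow_linear",
                  "garden"))))
  summarise <- function(mat, period) {
    tot <- sum(mat)
    reads <- vapply(levels_all, function(l)
      sum(mat[, lev == l, drop = FALSE]), 0)
    ntaxa <- vapply(levels_all, function(l)
      sum(colSums(mat[, lev == l, drop = FALSE]) > 0), 0L)
    data.frame(period = period, level = levels_all,
               prop_reads = if (tot > 0) unname(reads / tot) else NA_real_,
               n_taxa = unname(ntaxa), stringsAsFactors = FALSE)
  }
  out <- summarise(counts, "overall")
  if (!is.null(metadata)) {
    md <- metadata[match(rownames(counts), metadata$sample_id), , drop = FALSE]
    mo <- unique(md[c("year", "month")])
    mo <- mo[order(order_ym(mo$year, mo$month)), , drop = FALSE]
    for (i in seq_len(nrow(mo))) {
      sel <- md$year == mo$year[i] & md$month == mo$month[i]
      out <- rbind(out, summarise(counts[sel, , drop = FALSE],
                                  sprintf("%d-%02d", mo$year[i], mo$month[i])))
    }
  }
  attr(out, "excluded_reads") <- sum(trt$counts[, fam, drop = FALSE])
  out
}

#' Cross-year consistency of forage categories
#'
#' For each taxon, the highest category attained in any month of each year,
#' and a cross-year label: `<category>_both_years` when the yearly maxima
#' agree, `<category>_one_year` when the (higher) category is reached in one
#' year only, `absent` when never detected.
#'
#' @param monthly data.frame from [monthly_rra()] (needs >= 2 years).
#' @return data.frame: `taxon`, one `best_<year>` column per year,
#'   `consistency`.
#' @export
forage_consistency <- function(monthly) {
  years <- sort(unique(monthly$year))
  if (length(years) < 2L) stop_hf("need categories from at least two years")
  lv <- levels(categorize_rra(0))
  taxa <- unique(monthly$taxon)
  best <- sapply(years, function(y) {
    vapply(taxa, function(tx) {
      cats <- monthly$category[monthly$year == y & monthly$taxon == tx]
      if (!length(cats)) "absent" else lv[max(as.integer(cats))]
    }, character(1))
  })
  colnames(best) <- paste0("best_", years)
  consistency <- apply(best, 1, function(b) {
    b <- factor(b, levels = lv, ordered = TRUE)
    top <- lv[max(as.integer(b))]
    if (top == "absent") return("absent")
    n_at_top <- sum(b == top)
    if (n_at_top == length(b)) paste0(top, "_both_years")
    else paste0(top, "_one_year")
  })
  out <- data.frame(taxon = taxa, best, consistency,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}
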