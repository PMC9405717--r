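#' Construct and validate a floral survey
#'
#' Observations of species in flower, one row per (zone, year, month,
#' species). A surveyed month in which nothing flowered can be encoded with
#' `species = NA` so the month still counts as surveyed. Species must
#' resolve in the taxonomy.
#'
#' @param df data.frame with columns `zone_id`, `year`, `month`, `species`.
#' @param taxonomy a [taxonomy_table()] used to resolve species to genus.
#' @return validated data.frame of class `floral_survey`.
#' @export
floral_survey <- function(df, taxonomy) {
  req <- c("zone_id", "year", "month", "species")
  if (!all(req %in% names(df))) stop_hf("survey needs columns: ",
                                        paste(req, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$species[!is.na(df$species)] <-
    normalize_binomial(df$species[!is.na(df$species)])
  bad <- !is.na(df$species) & !(df$species %in% taxonomy$species_name)
  if (any(bad))
    stop_hf("survey species not in taxonomy: ",
            paste(unique(df$species[bad]), collapse = ", "))
  if (anyDuplicated(df[c("zone_id", "year", "month", "species")]))
    stop_hf("duplicate (zone, year, month, species) rows in survey")
  class(df) <- c("floral_survey", "data.frame")
  df
}

#' @rdname floral_survey
#' @param path TSV with the survey columns.
#' @export
read_survey_tsv <- function(path, taxonomy) {
  floral_survey(data.table::fread(path, sep = "\t", data.table = FALSE,
                                  na.strings = c("", "NA")), taxonomy)
}

surveyed_months <- function(survey) {
  unique(as.data.frame(survey)[c("year", "month")])
}

#' Genera in flower in a given month
#'
#' Union over all survey zones of the genera of species recorded in flower
#' in (year, month). Errors when the month was not surveyed at all.
#'
#' @param survey a [floral_survey()].
#' @param taxonomy a [taxonomy_table()].
#' @param year,month the month to query.
#' @return character vector (set) of genera.
#' @export
genera_in_flower <- function(survey, taxonomy, year, month) {
  sel <- survey$year == year & survey$month == month
  if (!any(sel)) stop_hf("month ", year, "-", month, " absent from survey")
  sp <- unique(survey$species[sel])
  sp <- sp[!is.na(sp)]
  sort(unique(taxonomy$genus[match(sp, taxonomy$species_name)]))
}

#' Map honey taxa to genera for the survey comparison
#'
#' Species-rank taxa map to their genus and genus-rank taxa to themselves.
#' Tribe- and family-rank taxa are expanded to the survey-recorded genera of
#' that tribe/family (each counted as detected in honey); when the survey
#' records none, the taxon is kept once as an unresolved pseudo-genus so it
#' still counts toward the honey tally. The expansion is logged in the
#' result.
#'
#' @param trt a `taxon_read_table`.
#' @param taxonomy a [taxonomy_table()].
#' @param survey a [floral_survey()].
#' @return list: `genera` (named list, taxon -> genus set), `log`
#'   (data.frame of tribe/family expansions).
#' @export
honey_genus_map <- function(trt, taxonomy, survey) {
  surveyed_sp <- unique(survey$species[!is.na(survey$species)])
  surveyed <- taxonomy[taxonomy$species_name %in% surveyed_sp, , drop = FALSE]
  genera <- vector("list", nrow(trt$taxa))
  names(genera) <- trt$taxa$taxon
  log <- list()
  for (i in seq_len(nrow(trt$taxa))) {
    tx <- trt$taxa$taxon[i]; rk <- trt$taxa$rank[i]
    g <- switch(rk,
      species = taxonomy$genus[match(tx, taxonomy$species_name)],
      genus = tx,
      tribe = sort(unique(surveyed$genus[!is.na(surveyed$tribe) &
                                           surveyed$tribe == tx])),
      family = sort(unique(surveyed$genus[surveyed$family == tx])))
    if (rk %in% c("tribe", "family")) {
      if (!length(g)) g <- paste0("unresolved:", tx)
      log[[length(log) + 1L]] <- data.frame(
        taxon = tx, rank = rk, genera = paste(g, collapse = ","),
        stringsAsFactors = FALSE)
    }
    genera[[i]] <- g
  }
  list(genera = genera,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(taxon = character(), rank = character(),
                    genera = character()))
}

honey_genera_in_month <- function(trt, metadata, taxonomy, survey,
                                  year, month) {
  ids <- metadata$sample_id[metadata$year == year & metadata$month == month]
  ids <- intersect(ids, rownames(trt$counts))
  if (!length(ids)) stop_hf("no honey samples for ", year, "-", month)
  present <- colnames(trt$counts)[colSums(
    trt$counts[ids, , drop = FALSE]) > 0]
  map <- honey_genus_map(trt, taxonomy, survey)
  sort(unique(unlist(map$genera[present])))
}

#' Compare honey genera with flowering genera for one month
#'
#' Either pass a `taxon_read_table` plus sample metadata (the genera detected
#' in honey are derived via [honey_genus_map()]), or pass the three counts
#' directly through `n_in_flower`, `n_in_honey`, `n_overlap` (e.g. to
#' recompute a published table's derived cells from its count rows).
#' Percentages are rounded half-up to integers: overlap percentage relative
#' to genera found in honey, proportion-used percentage relative to genera
#' in flower.
#'
#' @param honey a `taxon_read_table`, or `NULL` when counts are supplied.
#' @param survey a [floral_survey()] (ignored when counts are supplied).
#' @param year,month month compared.
#' @param taxonomy a [taxonomy_table()].
#' @param metadata data.frame `sample_id`, `year`, `month`.
#' @param n_in_flower,n_in_honey,n_overlap optional direct counts.
#' @return one-row data.frame: `year`, `month`, `n_genera_in_flower`,
#'   `n_genera_in_honey`, `n_overlap`, `overlap_pct`, `proportion_used_pct`.
#' @export
compare_month <- function(honey = NULL, survey = NULL, year = NA, month = NA,
                          taxonomy = NULL, metadata = NULL,
                          n_in_flower = NULL, n_in_honey = NULL,
                          n_overlap = NULL) {
  if (is.null(n_in_flower)) {
    flower <- genera_in_flower(survey, taxonomy, year, month)
    hg <- honey_genera_in_month(honey, metadata, taxonomy, survey, year, month)
    n_in_flower <- length(flower)
    n_in_honey <- length(hg)
    n_overlap <- length(intersect(hg, flower))
  }
  if (n_in_flower == 0) stop_hf("no genera in flower in ", year, "-", month,
                                ": proportion undefined")
  if (n_overlap > min(n_in_flower, n_in_honey))
    stop_hf("overlap exceeds its bounds")
  data.frame(year = year, month = month,
             n_genera_in_flower = n_in_flower,
             n_genera_in_honey = n_in_honey,
             n_overlap = n_overlap,
             overlap_pct = round_half_up(100 * n_overlap / n_in_honey),
             proportion_used_pct = round_half_up(100 * n_overlap / n_in_flower))
}

#' Month-by-month honey/survey comparison table
#'
#' One [compare_month()] row per surveyed month with honey samples, in
#' chronological order (the shape of a published availability table).
#'
#' @inheritParams compare_month
#' @export
comparison_table <- function(honey, survey, taxonomy, metadata) {
  mo <- unique(metadata[c("year", "month")])
  mo <- mo[order(order_ym(mo$year, mo$month)), , drop = FALSE]
  mo <- mo[paste(mo$year, mo$month) %in%
             paste(surveyed_months(survey)$year, surveyed_months(survey)$month),
           , drop = FALSE]
  out <- lapply(seq_len(nrow(mo)), function(i)
    compare_month(honey, survey, mo$year[i], mo$month[i], taxonomy, metadata))
  do.call(rbind, out)
}

#' Read fraction attributable to taxa flowering only in previous months
#'
#' For a given month, the read-weighted fraction of honey reads from taxa
#' whose genera were not in flower that month but had been in flower in at
#' least one earlier surveyed month (carryover from stored honey). Taxa
#' never recorded in any survey are excluded from the carryover fraction and
#' reported separately.
#'
#' @inheritParams compare_month
#' @return list: `fraction` in [0, 1], `taxa` (data.frame of contributing
#'   taxa with reads), `never_surveyed` (data.frame of excluded taxa).
#' @export
carryover_reads <- function(honey, survey, taxonomy, metadata, year, month) {
  months <- surveyed_months(survey)
  earlier <- months[order_ym(months$year, months$month) <
                      order_ym(year, month), , drop = FALSE]
  ids <- metadata$sample_id[metadata$year == year & metadata$month == month]
  ids <- intersect(ids, rownames(honey$counts))
  reads <- colSums(honey$counts[ids, , drop = FALSE])
  reads <- reads[reads > 0]
  total <- sum(reads)
  now <- genera_in_flower(survey, taxonomy, year, month)
  before <- unique(unlist(lapply(seq_len(nrow(earlier)), function(j)
    genera_in_flower(survey, taxonomy, earlier$year[j], earlier$month[j]))))
  ever <- unique(c(before, unlist(lapply(seq_len(nrow(months)), function(j)
    genera_in_flower(survey, taxonomy, months$year[j], months$month[j])))))
  map <- honey_genus_map(honey, taxonomy, survey)
  cls <- vapply(names(reads), function(tx) {
    g <- map$genera[[tx]]
    if (!any(g %in% ever)) "never_surveyed"
    else if (any(g %in% now)) "in_flower"
    else if (any(g %in% before)) "carryover"
    else "other"
  }, character(1))
  carry <- reads[cls == "carryover"]
  list(fraction = if (total > 0) sum(carry) / total else 0,
       taxa = data.frame(taxon = names(carry), reads = unname(carry),
                         stringsAsFactors = FALSE),
       never_surveyed = data.frame(
         taxon = names(reads)[cls == "never_surveyed"],
         reads = unname(reads[cls == "never_surveyed"]),
         stringsAsFactors = FALSE))
}
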