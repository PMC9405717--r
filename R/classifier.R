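#' Alignment scoring parameters
#'
#' Defaults follow megablast-like scoring: match +1, mismatch -2, gap opening
#' 0 and gap extension 2.5 (each gap base costs 2.5), with the corresponding
#' Karlin-Altschul constants used to express raw local-alignment scores S in
#' bits: `bitscore = (lambda * S - ln K) / ln 2`.
#'
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_extend gap penalties (a gap of length g costs
#'   `gap_open + g * gap_extend`).
#' @param lambda,K Karlin-Altschul parameters of the scoring system.
#' @param band half-width of the alignment band around the main diagonal.
#' @param seed_k exact-seed length used to pre-screen references
#'   (`0` scores every reference).
#' @return list of scoring parameters.
#' @export
alignment_params <- function(match = 1, mismatch = -2, gap_open = 0,
                             gap_extend = 2.5, lambda = 1.28, K = 0.46,
                             band = 30L, seed_k = 14L) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend, lambda = lambda, K = K,
       band = as.integer(band), seed_k = as.integer(seed_k))
}

#' Score a query against the reference database and rank hits
#'
#' Gapped local alignment of the query against every candidate reference
#' (after an exact-seed screen), converted to bitscores and sorted
#' decreasingly. The list is truncated to `top_n` hits, except that hits tied
#' (to relative tolerance `tie_tol`) with the `top_n`-th bitscore are all
#' retained.
#'
#' @param query nucleotide string (non-empty).
#' @param db reference database (data.frame with `record_id`, `label`,
#'   `label_rank`, `sequence`).
#' @param top_n number of hits to keep (default 20).
#' @param params scoring parameters from [alignment_params()].
#' @param tie_tol relative bitscore tolerance treating hits as tied.
#' @return data.frame of hits: `record_id`, `label`, `label_rank`,
#'   `bitscore`, `identity_pct`, sorted by bitscore (desc).
#' @export
align_and_rank <- function(query, db, top_n = 20L,
                           params = alignment_params(), tie_tol = 1e-9) {
  res <- align_clusters(query, db, top_n = top_n, params = params,
                        tie_tol = tie_tol)
  res[[1]]
}

#' Batch version of [align_and_rank()] over many queries
#'
#' @param queries character vector of cluster representative sequences.
#' @inheritParams align_and_rank
#' @return list of hit data.frames, one per query.
#' @export
align_clusters <- function(queries, db, top_n = 20L,
                           params = alignment_params(), tie_tol = 1e-9) {
  if (!nrow(db)) stop_hf("reference database is empty")
  if (any(!nzchar(queries))) stop_hf("empty query sequence")
  raw <- align_batch_cpp(queries, db$sequence,
                         params$match, params$mismatch, params$gap_open,
                         params$gap_extend, params$band, params$seed_k)
  lapply(raw, function(m) {
    bits <- (params$lambda * m[, "score"] - log(params$K)) / log(2)
    keep <- m[, "score"] > 0
    hits <- data.frame(
      record_id = db$record_id[m[keep, "ref"]],
      label = db$label[m[keep, "ref"]],
      label_rank = db$label_rank[m[keep, "ref"]],
      bitscore = bits[keep],
      identity_pct = 100 * m[keep, "matches"] / pmax(m[keep, "aln_len"], 1),
      stringsAsFactors = FALSE)
    hits <- hits[order(-hits$bitscore, hits$record_id), , drop = FALSE]
    if (nrow(hits) > top_n) {
      cut <- hits$bitscore[top_n]
      hits <- hits[hits$bitscore >= cut * (1 - 1e-12) |
                     seq_len(nrow(hits)) <= top_n, , drop = FALSE]
    }
    rownames(hits) <- NULL
    hits
  })
}

#' Top-bitscore consensus taxonomic assignment
#'
#' Applies the consensus rule to the set of hits sharing the maximal bitscore
#' (ties detected with relative tolerance `tie_tol`): a single species gives
#' a species-rank assignment; several species of one genus give the genus;
#' several genera within one tribe (or, failing that, one family) give that
#' tribe or family; families spanning more than one clade mark the sequence
#' as a putative chimera (`chimeric_excluded`). Several families within a
#' single clade have no defined rank and yield `unassigned`. Genus-rank
#' reference records vote at genus rank and can never produce a species
#' assignment.
#'
#' @param hits hit data.frame from [align_and_rank()] (bitscore-descending).
#' @param taxonomy a [taxonomy_table()].
#' @param cluster_id optional id copied into the result.
#' @param tie_tol relative bitscore tolerance for the top-score set.
#' @return one-row data.frame: `cluster_id`, `status`
#'   (`assigned`/`chimeric_excluded`/`unassigned`), `rank`, `taxon`,
#'   `best_bitscore`, `n_top_hits`, `supporting_hits` (comma-separated
#'   record ids).
#' @export
assign_taxon <- function(hits, taxonomy, cluster_id = NA_character_,
                         tie_tol = 1e-9) {
  verdict <- function(status, rank = NA_character_, taxon = NA_character_,
                      best = NA_real_, top = NULL) {
    data.frame(cluster_id = cluster_id, status = status, rank = rank,
               taxon = taxon, best_bitscore = best,
               n_top_hits = length(top),
               supporting_hits = paste(top, collapse = ","),
               stringsAsFactors = FALSE)
  }
  if (is.null(hits) || !nrow(hits)) return(verdict("unassigned"))
  best <- max(hits$bitscore)
  top <- hits[hits$bitscore >= best * (1 - tie_tol), , drop = FALSE]
  lin <- resolve_labels(taxonomy, top$label, top$label_rank)
  sp <- unique(top$label[top$label_rank == "species"])
  if (all(top$label_rank == "species") && length(sp) == 1L)
    return(verdict("assigned", "species", normalize_binomial(sp), best,
                   top$record_id))
  if (length(unique(lin$genus)) == 1L)
    return(verdict("assigned", "genus", lin$genus[1], best, top$record_id))
  tribes <- unique(lin$tribe)
  if (length(tribes) == 1L && !anyNA(tribes))
    return(verdict("assigned", "tribe", tribes[1], best, top$record_id))
  fams <- unique(lin$family)
  if (length(fams) == 1L)
    return(verdict("assigned", "family", fams[1], best, top$record_id))
  if (length(unique(lin$clade)) == 1L)
    return(verdict("unassigned", best = best, top = top$record_id))
  verdict("chimeric_excluded", best = best, top = top$record_id)
}

#' Classify every cluster of a cluster table
#'
#' @param table a `cluster_table` from [dereplicate_and_cluster()].
#' @param db reference database from [build_reference_database()].
#' @param taxonomy a [taxonomy_table()].
#' @inheritParams align_and_rank
#' @return data.frame of assignments, one row per cluster.
#' @export
classify_clusters <- function(table, db, taxonomy, top_n = 20L,
                              params = alignment_params(), tie_tol = 1e-9) {
  hits <- align_clusters(table$clusters$representative_sequence, db,
                         top_n = top_n, params = params, tie_tol = tie_tol)
  out <- mapply(assign_taxon, hits, table$clusters$cluster_id,
                MoreArgs = list(taxonomy = taxonomy, tie_tol = tie_tol),
                SIMPLIFY = FALSE)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Aggregate cluster counts into a samples x taxa read table
#'
#' Sums, per sample, the counts of clusters sharing an assigned (rank, taxon)
#' pair. Chimeric and unassigned clusters accumulate into a discard tally.
#' Also computes the rank-level breakdown of assigned reads (fraction at
#' species/genus/tribe/family).
#'
#' @param table a `cluster_table`.
#' @param assignments data.frame from [classify_clusters()] (one row per
#'   cluster of `table`).
#' @return a `taxon_read_table`: list with `counts` (samples x taxa integer
#'   matrix), `taxa` (data.frame `taxon`, `rank`), `discards` (reads per
#'   non-assigned status), `rank_breakdown` (named fractions).
#' @export
aggregate_reads <- function(table, assignments) {
  ids <- table$clusters$cluster_id
  if (!all(assignments$cluster_id %in% ids) ||
      !all(ids %in% assignments$cluster_id))
    stop_hf("assignments and cluster table refer to different clusters")
  assignments <- assignments[match(ids, assignments$cluster_id), , drop = FALSE]
  ok <- assignments$status == "assigned"
  if (any(ok)) {
    key <- paste(assignments$rank[ok], assignments$taxon[ok], sep = "|")
    ukey <- unique(key)
    counts <- t(rowsum(table$counts[ok, , drop = FALSE], group = key,
                       reorder = FALSE))
    counts <- counts[, match(ukey, colnames(counts)), drop = FALSE]
    taxa <- data.frame(taxon = sub("^[^|]*\\|", "", ukey),
                       rank = sub("\\|.*$", "", ukey), stringsAsFactors = FALSE)
  } else {
    counts <- matrix(0L, ncol(table$counts), 0,
                     dimnames = list(colnames(table$counts), NULL))
    taxa <- data.frame(taxon = character(), rank = character(),
                       stringsAsFactors = FALSE)
  }
  colnames(counts) <- taxa$taxon
  ord <- order(-colSums(counts))
  counts <- counts[, ord, drop = FALSE]
  taxa <- taxa[ord, , drop = FALSE]
  rownames(taxa) <- NULL
  disc <- vapply(c("chimeric_excluded", "unassigned"), function(st)
    sum(table$counts[assignments$status == st, , drop = FALSE]), 0)
  reads_by_rank <- vapply(c("species", "genus", "tribe", "family"),
    function(r) sum(counts[, taxa$rank == r, drop = FALSE]), 0)
  total <- sum(counts)
  structure(list(counts = counts, taxa = taxa, discards = disc,
                 rank_breakdown = if (total > 0) reads_by_rank / total
                                  else reads_by_rank),
            class = "taxon_read_table")
}

#' @export
print.taxon_read_table <- function(x, ...) {
  cat(sprintf("taxon_read_table: %d samples x %d taxa, %s assigned reads\n",
              nrow(x$counts), ncol(x$counts), format(sum(x$counts))))
  rb <- round(100 * x$rank_breakdown)
  cat(sprintf("  rank breakdown: %s\n",
              paste(names(rb), paste0(rb, "%"), sep = " ", collapse = ", ")))
  cat(sprintf("  discarded reads: chimeric %s, unassigned %s\n",
              format(x$discards[["chimeric_excluded"]]),
              format(x$discards[["unassigned"]])))
  invisible(x)
}

#' Botanical-veracity verification flags
#'
#' Flags (never removes) assigned taxa for human review against the floral
#' survey: `not_in_survey` when the taxon's genus was never recorded in any
#' survey, `carryover_candidate` when it was detected in a month in which it
#' was not in flower but had flowered in an earlier surveyed month, and
#' `out_of_season` when it was detected before ever being recorded in
#' flower.
#'
#' @param trt a `taxon_read_table` from [aggregate_reads()].
#' @param metadata data.frame with `sample_id`, `year`, `month` matching the
#'   table's samples.
#' @param survey a [floral_survey()].
#' @param taxonomy a [taxonomy_table()].
#' @return data.frame: `year`, `month`, `taxon`, `genus`, `flag`.
#' @export
verification_report <- function(trt, metadata, survey, taxonomy) {
  map <- honey_genus_map(trt, taxonomy, survey)
  months <- surveyed_months(survey)
  out <- list()
  for (i in seq_len(nrow(metadata))) {
    sm <- metadata[i, ]
    row <- trt$counts[sm$sample_id, , drop = TRUE]
    present <- names(row)[row > 0]
    for (tx in present) {
      gset <- map$genera[[tx]]
      gset <- gset[!is.na(gset)]
      now <- genera_in_flower(survey, taxonomy, sm$year, sm$month)
      earlier <- months[order_ym(months$year, months$month) <
                          order_ym(sm$year, sm$month), , drop = FALSE]
      before <- unique(unlist(lapply(seq_len(nrow(earlier)), function(j)
        genera_in_flower(survey, taxonomy, earlier$year[j], earlier$month[j]))))
      ever <- unique(c(before, unlist(lapply(seq_len(nrow(months)), function(j)
        genera_in_flower(survey, taxonomy, months$year[j], months$month[j])))))
      flag <- if (!any(gset %in% ever)) "not_in_survey"
        else if (any(gset %in% now)) NA_character_
        else if (any(gset %in% before)) "carryover_candidate"
        else "out_of_season"
      if (!is.na(flag))
        out[[length(out) + 1L]] <- data.frame(
          year = sm$year, month = sm$month, taxon = tx,
          genus = paste(gset, collapse = ","), flag = flag,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(year = integer(), month = integer(), taxon = character(),
                      genus = character(), flag = character()))
  unique(do.call(rbind, out))
}

order_ym <- function(year, month) year * 12L + month
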