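#' Read and write reference sequence pools
#'
#' Reference records travel as FASTA with headers `record_id|label|rank`,
#' where rank is `species` or `genus`. In memory a pool is a data.frame with
#' columns `record_id`, `label`, `label_rank`, `sequence` (alphabet ACGTN).
#'
#' @param path FASTA file path.
#' @return `read_reference_fasta` returns a reference pool data.frame.
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  hdr <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(hdr) != 3L))
    stop_hf("reference FASTA headers must be 'record_id|label|rank'")
  hdr <- do.call(rbind, hdr)
  pool <- data.frame(record_id = hdr[, 1], label = hdr[, 2],
                     label_rank = hdr[, 3],
                     sequence = as.character(seqs),
                     stringsAsFactors = FALSE)
  validate_pool(pool)
}

#' @rdname read_reference_fasta
#' @param pool reference pool or database data.frame.
#' @export
write_reference_fasta <- function(pool, path) {
  seqs <- Biostrings::DNAStringSet(pool$sequence)
  names(seqs) <- paste(pool$record_id, pool$label, pool$label_rank, sep = "|")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

validate_pool <- function(pool) {
  stopifnot(all(c("record_id", "label", "label_rank", "sequence") %in% names(pool)))
  if (any(!nzchar(pool$sequence)))
    stop_hf("reference records must have non-empty sequences")
  bad <- grepl("[^ACGTN]", pool$sequence)
  if (any(bad))
    stop_hf("reference sequences restricted to A/C/G/T/N; offending records: ",
            paste(head(pool$record_id[bad], 5), collapse = ", "))
  if (!all(pool$label_rank %in% c("species", "genus")))
    stop_hf("label_rank must be 'species' or 'genus'")
  pool
}

#' Build the curated reference database
#'
#' Keeps every pool record whose species-rank label is on the species list.
#' For each listed species with no species-rank record in the pool, pool
#' records labelled with that species' genus (at genus rank) are added as a
#' fallback, tagged `genus_fallback`. Species names that do not resolve in
#' the taxonomy are collected into the `"skipped"` attribute. The result is
#' deterministic given its inputs and idempotent under rebuilding.
#'
#' @param species_list character vector of binomials (see [species_list()]).
#' @param record_pool reference pool data.frame (see [read_reference_fasta()]).
#' @param taxonomy a [taxonomy_table()].
#' @return data.frame of records with a `provenance` column
#'   (`species_match`/`genus_fallback`) and attribute `skipped`.
#' @export
build_reference_database <- function(species_list, record_pool, taxonomy) {
  record_pool <- validate_pool(as.data.frame(record_pool))
  names_in <- unique(normalize_binomial(species_list))
  resolved <- names_in %in% taxonomy$species_name
  skipped <- names_in[!resolved]
  listed <- names_in[resolved]
  if (!length(listed)) stop_hf("no species-list name resolves in the taxonomy")

  # infraspecific species labels truncate to the binomial before matching
  pool_lab <- ifelse(record_pool$label_rank == "species",
                     normalize_binomial(record_pool$label), record_pool$label)

  sp_hit <- record_pool$label_rank == "species" & pool_lab %in% listed
  covered_sp <- unique(pool_lab[sp_hit])
  missing_sp <- setdiff(listed, covered_sp)
  missing_gen <- unique(taxonomy$genus[match(missing_sp, taxonomy$species_name)])
  gen_hit <- record_pool$label_rank == "genus" & pool_lab %in% missing_gen

  db <- record_pool[sp_hit | gen_hit, , drop = FALSE]
  if (!nrow(db)) stop_hf("resulting reference database is empty")
  db$label <- pool_lab[sp_hit | gen_hit]
  db$provenance <- ifelse(db$label_rank == "species", "species_match",
                          "genus_fallback")
  db <- db[!duplicated(db$record_id), , drop = FALSE]
  rownames(db) <- NULL
  attr(db, "skipped") <- skipped
  attr(db, "species_list") <- listed
  class(db) <- c("reference_db", "data.frame")
  db
}

#' Reference database coverage statistics
#'
#' Species coverage: share of listed species with at least one species-rank
#' record. Genus coverage: share of listed species whose genus carries at
#' least one record at any rank (a congener's species record counts).
#' Percentages are reported to the nearest integer in the printed summary;
#' raw values are returned.
#'
#' @param db database from [build_reference_database()] (or any record
#'   data.frame with `label`/`label_rank`).
#' @param species_list character vector of binomials.
#' @param taxonomy a [taxonomy_table()].
#' @return list with `species_pct`, `genus_pct`, and logical vectors
#'   `species_covered`, `genus_covered` named by species.
#' @export
coverage_stats <- function(db, species_list, taxonomy) {
  listed <- unique(normalize_binomial(species_list))
  listed <- listed[listed %in% taxonomy$species_name]
  if (!length(listed)) stop_hf("species list empty or unresolvable")
  gen_of <- taxonomy$genus[match(listed, taxonomy$species_name)]
  db <- as.data.frame(db)
  sp_recs <- normalize_binomial(db$label[db$label_rank == "species"])
  rec_genus <- ifelse(db$label_rank == "species",
                      taxonomy$genus[match(normalize_binomial(db$label),
                                           taxonomy$species_name)],
                      db$label)
  species_covered <- setNames(listed %in% sp_recs, listed)
  genus_covered <- setNames(gen_of %in% rec_genus, listed)
  # a species-rank record for the species itself also covers its genus
  genus_covered <- genus_covered | species_covered
  out <- list(species_pct = 100 * mean(species_covered),
              genus_pct = 100 * mean(genus_covered),
              species_covered = species_covered,
              genus_covered = genus_covered)
  class(out) <- "coverage_report"
  out
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("reference coverage: species %d%%, genus %d%% (n = %d listed species)\n",
              round_half_up(x$species_pct), round_half_up(x$genus_pct),
              length(x$species_covered)))
  invisible(x)
}
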