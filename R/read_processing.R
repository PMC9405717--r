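#' Quality-trim paired reads
#'
#' Sliding-window trim in the style of Trimmomatic's SLIDINGWINDOW step:
#' full windows are scanned from the 5' end and the read is cut at the start
#' of the first window whose mean Phred quality falls below the threshold,
#' removing the low-quality 3' tail. A pair is discarded when either mate is
#' trimmed below `min_len`.
#'
#' @param pairs a `read_pairs` object: list with character vectors `seq1`,
#'   `qual1`, `seq2`, `qual2` (Phred+33 strings) and `sample_id`.
#' @param window_len window size in bases (default 4).
#' @param mean_q_threshold mean Phred quality below which a window fails
#'   (default 20).
#' @param min_len minimum mate length after trimming (default 100).
#' @return trimmed `read_pairs`; discarded pairs are dropped and counted in
#'   the `"n_discarded"` attribute.
#' @export
quality_trim <- function(pairs, window_len = 4L, mean_q_threshold = 20,
                         min_len = 100L) {
  stopifnot(window_len >= 1L)
  pairs <- as_read_pairs(pairs)
  tr <- trim_pairs_cpp(pairs$seq1, pairs$qual1, pairs$seq2, pairs$qual2,
                       as.integer(window_len), mean_q_threshold,
                       as.integer(min_len))
  keep <- tr$keep
  out <- read_pairs(tr$seq1[keep], tr$qual1[keep], tr$seq2[keep],
                    tr$qual2[keep], pairs$sample_id[keep])
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Merge read pairs by best ungapped overlap
#'
#' Read 1 is overlapped with the reverse complement of read 2 at the offset
#' maximizing the number of matching bases. The merge is accepted when the
#' overlap is at least `min_overlap` bases with a mismatch fraction at most
#' `max_mismatch_frac`; within the overlap the higher-quality base is kept.
#' Merged reads shorter than `min_merged_len` (450 bp by default, the rbcL
#' amplicon length filter) are discarded.
#'
#' @inheritParams quality_trim
#' @param min_overlap minimum acceptable overlap (default 10).
#' @param max_mismatch_frac maximum mismatch fraction in the overlap
#'   (default 0.25).
#' @param min_merged_len minimum merged length (default 450).
#' @return a `merged_reads` object: list with `sequence` and `sample_id`,
#'   plus a per-reason discard tally in attribute `"discards"`.
#' @export
merge_pairs <- function(pairs, min_overlap = 10L, max_mismatch_frac = 0.25,
                        min_merged_len = 450L) {
  pairs <- as_read_pairs(pairs)
  mg <- merge_pairs_cpp(pairs$seq1, pairs$qual1, pairs$seq2, pairs$qual2,
                        as.integer(min_overlap), max_mismatch_frac,
                        as.integer(min_merged_len))
  ok <- mg$status == 0L
  out <- structure(list(sequence = mg$merged[ok],
                        sample_id = pairs$sample_id[ok]),
                   class = "merged_reads")
  attr(out, "discards") <- c(no_overlap = sum(mg$status == 1L),
                             too_short = sum(mg$status == 2L))
  out
}

#' Construct a read-pair set
#'
#' @param seq1,seq2 character vectors of mate sequences.
#' @param qual1,qual2 Phred+33 quality strings, same lengths as the mates.
#' @param sample_id character vector of sample ids (recycled).
#' @return a `read_pairs` list object.
#' @export
read_pairs <- function(seq1, qual1, seq2, qual2, sample_id) {
  n <- length(seq1)
  qual1 <- rep_len(as.character(qual1), n)
  qual2 <- rep_len(as.character(qual2), n)
  if (any(nchar(seq1) != nchar(qual1)) || any(nchar(seq2) != nchar(qual2)))
    stop_hf("sequence and quality strings must have equal lengths per mate")
  structure(list(seq1 = unname(as.character(seq1)), qual1 = unname(qual1),
                 seq2 = unname(as.character(seq2)), qual2 = unname(qual2),
                 sample_id = rep_len(as.character(sample_id), n)),
            class = "read_pairs")
}

as_read_pairs <- function(x) {
  if (!inherits(x, "read_pairs")) stop_hf("expected a read_pairs object")
  x
}

#' Dereplicate and cluster merged reads at 100% identity
#'
#' One cluster per distinct full-length sequence, counted per sample across
#' all samples simultaneously; clusters whose total count across samples is 1
#' (singletons) are discarded. Clusters are ordered by total count
#' (decreasing) then sequence (lexicographic), so the result is invariant to
#' input read order.
#'
#' @param reads a `merged_reads` object (or list with `sequence`,
#'   `sample_id`).
#' @param samples optional character vector fixing the sample (column) order;
#'   defaults to sorted unique sample ids.
#' @return a `cluster_table`: list with `clusters` (data.frame `cluster_id`,
#'   `representative_sequence`, `total`) and `counts` (cluster x sample
#'   integer matrix). Attribute `"n_singletons"` counts removed reads.
#' @export
dereplicate_and_cluster <- function(reads, samples = NULL) {
  seqs <- reads$sequence
  sid <- reads$sample_id
  samples <- samples %||% sort(unique(sid))
  if (!length(seqs)) {
    warning("no merged reads to cluster; returning empty table")
    return(empty_cluster_table(samples))
  }
  dt <- data.table::data.table(sequence = seqs, sample_id = sid)
  agg <- dt[, .N, by = .(sequence, sample_id)]
  tot <- agg[, .(total = sum(N)), by = sequence]
  keep <- tot[total >= 2L]
  n_singletons <- nrow(tot) - nrow(keep)
  if (!nrow(keep)) {
    warning("all clusters are singletons; returning empty table")
    out <- empty_cluster_table(samples)
    attr(out, "n_singletons") <- n_singletons
    return(out)
  }
  data.table::setorder(keep, -total, sequence)
  keep[, cluster_id := sprintf("cluster_%05d", .I)]
  agg <- agg[keep, on = "sequence", nomatch = NULL]
  counts <- matrix(0L, nrow = nrow(keep), ncol = length(samples),
                   dimnames = list(keep$cluster_id, samples))
  counts[cbind(match(agg$cluster_id, keep$cluster_id),
               match(agg$sample_id, samples))] <- agg$N
  out <- structure(list(
    clusters = data.frame(cluster_id = keep$cluster_id,
                          representative_sequence = keep$sequence,
                          total = keep$total, stringsAsFactors = FALSE),
    counts = counts), class = "cluster_table")
  attr(out, "n_singletons") <- n_singletons
  out
}

empty_cluster_table <- function(samples) {
  structure(list(
    clusters = data.frame(cluster_id = character(),
                          representative_sequence = character(),
                          total = integer(), stringsAsFactors = FALSE),
    counts = matrix(0L, 0, length(samples),
                    dimnames = list(NULL, samples))),
    class = "cluster_table")
}

#' Exclude low-depth samples from a cluster table
#'
#' Samples whose retained read count (column sum) is strictly below
#' `min_reads` are dropped and reported; clusters left with zero reads are
#' pruned. Mirrors the study-design rule that samples returning fewer than
#' 100 sequences are excluded from analysis.
#'
#' @param table a `cluster_table`.
#' @param min_reads exclusion threshold (default 100; strict `<`).
#' @return filtered `cluster_table` with attribute `"excluded"` (data.frame
#'   sample_id, reads).
#' @export
filter_samples <- function(table, min_reads = 100L) {
  depth <- colSums(table$counts)
  drop <- depth < min_reads
  if (all(drop)) stop_hf("all samples fall below ", min_reads, " reads")
  excl <- data.frame(sample_id = names(depth)[drop],
                     reads = unname(depth[drop]), stringsAsFactors = FALSE)
  counts <- table$counts[, !drop, drop = FALSE]
  live <- rowSums(counts) > 0
  out <- structure(list(clusters = table$clusters[live, , drop = FALSE],
                        counts = counts[live, , drop = FALSE]),
                   class = "cluster_table")
  rownames(out$clusters) <- NULL
  attr(out, "excluded") <- excl
  attr(out, "n_singletons") <- attr(table, "n_singletons")
  out
}

#' Run the full read-processing stage
#'
#' Convenience wrapper: trim, merge, dereplicate/cluster and filter samples,
#' returning the cluster table plus a per-stage read-count log.
#'
#' @param pairs a `read_pairs` object covering all samples.
#' @param trim,merge,filter lists of arguments forwarded to [quality_trim()],
#'   [merge_pairs()] and [filter_samples()].
#' @return list with `table` (a `cluster_table`) and `log` (named counts per
#'   stage).
#' @export
process_reads <- function(pairs, trim = list(), merge = list(),
                          filter = list()) {
  n0 <- length(pairs$seq1)
  trimmed <- do.call(quality_trim, c(list(pairs), trim))
  merged <- do.call(merge_pairs, c(list(trimmed), merge))
  tab <- dereplicate_and_cluster(merged,
                                 samples = sort(unique(pairs$sample_id)))
  tab <- do.call(filter_samples, c(list(tab), filter))
  list(table = tab,
       log = c(input_pairs = n0,
               after_trim = length(trimmed$seq1),
               merged = length(merged$sequence),
               singletons_removed = attr(tab, "n_singletons") %||% 0L,
               clusters = nrow(tab$clusters),
               samples_excluded = nrow(attr(tab, "excluded"))))
}

#' Read / write paired FASTQ with a sample sheet
#'
#' The sample sheet is a TSV with columns `sample_id`, `fastq1`, `fastq2`
#' and optional metadata (`apiary`, `month`, `year`). Paths are resolved
#' relative to the sheet's directory.
#'
#' @param sheet_path sample sheet TSV path.
#' @return list with `pairs` (a `read_pairs`) and `metadata` (data.frame).
#' @export
read_fastq_pairs <- function(sheet_path) {
  sheet <- data.table::fread(sheet_path, sep = "\t", data.table = FALSE)
  stopifnot(all(c("sample_id", "fastq1", "fastq2") %in% names(sheet)))
  base <- dirname(sheet_path)
  res <- lapply(seq_len(nrow(sheet)), function(i) {
    f1 <- file.path(base, sheet$fastq1[i]); f2 <- file.path(base, sheet$fastq2[i])
    # plain-character conversion; the mcols dropped on read carry nothing
    suppressWarnings({
      r1 <- Biostrings::readQualityScaledDNAStringSet(f1)
      r2 <- Biostrings::readQualityScaledDNAStringSet(f2)
      list(s1 = as.character(r1), q1 = as.character(Biostrings::quality(r1)),
           s2 = as.character(r2), q2 = as.character(Biostrings::quality(r2)),
           n = length(r1))
    })
  })
  pairs <- read_pairs(
    unlist(lapply(res, `[[`, "s1")), unlist(lapply(res, `[[`, "q1")),
    unlist(lapply(res, `[[`, "s2")), unlist(lapply(res, `[[`, "q2")),
    rep(sheet$sample_id, vapply(res, `[[`, 0L, "n")))
  list(pairs = pairs, metadata = sheet[setdiff(names(sheet),
                                               c("fastq1", "fastq2"))])
}

#' @rdname read_fastq_pairs
#' @param pairs a `read_pairs` object.
#' @param dir output directory; one `<sample>_R1.fastq`/`_R2.fastq` pair per
#'   sample plus `samples.tsv`.
#' @param metadata optional per-sample metadata merged into the sheet.
#' @export
write_fastq_pairs <- function(pairs, dir, metadata = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sort(unique(pairs$sample_id))
  sheet <- data.frame(sample_id = ids,
                      fastq1 = paste0(ids, "_R1.fastq"),
                      fastq2 = paste0(ids, "_R2.fastq"),
                      stringsAsFactors = FALSE)
  for (id in ids) {
    sel <- pairs$sample_id == id
    nm <- sprintf("%s_read%06d", id, seq_len(sum(sel)))
    for (mate in 1:2) {
      s <- Biostrings::DNAStringSet(pairs[[paste0("seq", mate)]][sel])
      q <- Biostrings::PhredQuality(pairs[[paste0("qual", mate)]][sel])
      names(s) <- nm
      Biostrings::writeXStringSet(
        s, file.path(dir, sheet[[paste0("fastq", mate)]][match(id, ids)]),
        format = "fastq", qualities = q)
    }
  }
  if (!is.null(metadata)) sheet <- merge(sheet, metadata, by = "sample_id")
  data.table::fwrite(sheet, file.path(dir, "samples.tsv"), sep = "\t")
  invisible(file.path(dir, "samples.tsv"))
}

#' Write a cluster table to disk
#'
#' Representatives as FASTA (`representatives.fasta`) and counts as TSV
#' (`counts.tsv`, clusters x samples with a `cluster_id` column).
#'
#' @param table a `cluster_table`.
#' @param dir output directory.
#' @export
write_cluster_table <- function(table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::DNAStringSet(table$clusters$representative_sequence)
  names(seqs) <- table$clusters$cluster_id
  Biostrings::writeXStringSet(seqs, file.path(dir, "representatives.fasta"))
  df <- data.frame(cluster_id = rownames(table$counts), table$counts,
                   check.names = FALSE)
  data.table::fwrite(df, file.path(dir, "counts.tsv"), sep = "\t")
  invisible(dir)
}

#' @rdname write_cluster_table
#' @export
read_cluster_table <- function(dir) {
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "representatives.fasta"))
  df <- data.table::fread(file.path(dir, "counts.tsv"), sep = "\t",
                          data.table = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$cluster_id
  clusters <- data.frame(
    cluster_id = unname(names(seqs)),
    representative_sequence = unname(as.character(seqs)),
    total = unname(rowSums(counts)[names(seqs)]),
    stringsAsFactors = FALSE)
  rownames(clusters) <- NULL
  structure(list(clusters = clusters, counts = counts),
            class = "cluster_table")
}
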