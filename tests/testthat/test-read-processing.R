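q_str <- function(q, n) strrep(rawToChar(as.raw(q + 33L)), n)

test_that("quality trimming follows the sliding-window oracle", {
  set.seed(21)
  # high-quality reads pass untouched
  p <- read_pairs(rand_seq(200), q_str(40, 200), rand_seq(200),
                  q_str(40, 200), "s1")
  out <- quality_trim(p, 4, 20, 100)
  expect_equal(out$seq1, p$seq1)
  expect_equal(out$seq2, p$seq2)
  # a uniform Q10 tail is cut at the first failing window
  qv <- c(rep(40L, 250), rep(10L, 50))
  qstr <- rawToChar(as.raw(qv + 33L))
  p2 <- read_pairs(rand_seq(300), qstr, rand_seq(300), q_str(40, 300), "s1")
  out2 <- quality_trim(p2, 4, 20, 100)
  cut <- trim_point_R(qv, 4L, 20)
  expect_equal(nchar(out2$seq1), cut)
  expect_equal(out2$seq1, substr(p2$seq1, 1, cut))
  # random quality profiles agree with the oracle
  for (i in 1:25) {
    qv <- sample(2:41, 150, TRUE)
    p3 <- read_pairs(rand_seq(150), rawToChar(as.raw(qv + 33L)),
                     rand_seq(150), q_str(40, 150), "s1")
    out3 <- quality_trim(p3, 5, 22, 0)
    expect_equal(nchar(out3$seq1), trim_point_R(qv, 5L, 22))
  }
})

test_that("pairs trimmed below the length floor are discarded", {
  p <- read_pairs(rand_seq(120), paste0(q_str(40, 20), q_str(2, 100)),
                  rand_seq(120), q_str(40, 120), "s1")
  out <- quality_trim(p, 4, 20, 100)
  expect_length(out$seq1, 0)
  expect_equal(attr(out, "n_discarded"), 1L)
})

test_that("merging reconstructs a known template from its pair", {
  set.seed(22)
  tpl <- rand_seq(500)
  p <- template_pair(tpl, 300)
  m <- merge_pairs(p, min_merged_len = 450)
  expect_equal(m$sequence, tpl)
  # higher-quality base wins inside the overlap
  s1 <- substr(tpl, 1, 300)
  s2r <- substr(tpl, 201, 500)
  substr(s1, 250, 250) <- if (substr(tpl, 250, 250) == "A") "C" else "A"
  p2 <- read_pairs(s1, paste0(q_str(30, 249), q_str(20, 51)), rc(s2r),
                   q_str(30, 300), "s1")
  m2 <- merge_pairs(p2, min_merged_len = 450)
  expect_equal(m2$sequence, tpl)  # read 2 outranks the low-quality mismatch
})

test_that("merged length filter is strict at 450", {
  set.seed(23)
  tpl449 <- rand_seq(449)
  tpl450 <- rand_seq(450)
  m449 <- merge_pairs(template_pair(tpl449, 300))
  m450 <- merge_pairs(template_pair(tpl450, 300))
  expect_length(m449$sequence, 0)
  expect_equal(attr(m449, "discards")[["too_short"]], 1L)
  expect_equal(m450$sequence, tpl450)
})

test_that("pairs without an acceptable overlap are discarded", {
  set.seed(24)
  p <- read_pairs(rand_seq(200), q_str(40, 200), rand_seq(200),
                  q_str(40, 200), "s1")
  m <- merge_pairs(p, min_overlap = 20, min_merged_len = 100)
  expect_length(m$sequence, 0)
  expect_equal(attr(m, "discards")[["no_overlap"]], 1L)
})

test_that("clustering counts per sample and drops all-sample singletons", {
  set.seed(25)
  a <- rand_seq(460); b <- rand_seq(460); lone <- rand_seq(460)
  reads <- merged_set(c(a, a, b, rep(b, 9), lone),
                      c("sA", "sB", "sA", rep("sA", 9), "sB"))
  tab <- dereplicate_and_cluster(reads)
  # a appears once in each of two samples: total 2, kept
  expect_equal(nrow(tab$clusters), 2L)
  ra <- which(tab$clusters$representative_sequence == a)
  expect_equal(unname(tab$counts[ra, c("sA", "sB")]), c(1L, 1L))
  # 10 identical reads collapse to one cluster of 10
  rb <- which(tab$clusters$representative_sequence == b)
  expect_equal(sum(tab$counts[rb, ]), 10L)
  # the lone read is gone, and reads are conserved
  expect_false(lone %in% tab$clusters$representative_sequence)
  expect_equal(sum(tab$counts) + attr(tab, "n_singletons"), 13L)
})

test_that("clustering is invariant to read order", {
  set.seed(26)
  seqs <- sample(replicate(6, rand_seq(100)), 60, TRUE)
  sid <- sample(c("s1", "s2", "s3"), 60, TRUE)
  t1 <- dereplicate_and_cluster(merged_set(seqs, sid))
  perm <- sample(60)
  t2 <- dereplicate_and_cluster(merged_set(seqs[perm], sid[perm]))
  expect_identical(t1, t2)
})

test_that("empty read sets warn and return an empty table", {
  expect_warning(tab <- dereplicate_and_cluster(merged_set(character(0),
                                                           character(0))),
                 "empty")
  expect_equal(nrow(tab$clusters), 0L)
})

test_that("sample exclusion is strict below the read threshold", {
  set.seed(27)
  a <- rand_seq(80); b <- rand_seq(80)
  reads <- merged_set(c(rep(a, 99), rep(b, 100), a),
                      c(rep("low", 99), rep("ok", 100), "ok"))
  tab <- dereplicate_and_cluster(reads)
  out <- filter_samples(tab, 100)
  expect_equal(colnames(out$counts), "ok")
  expect_equal(attr(out, "excluded")$sample_id, "low")
  expect_equal(attr(out, "excluded")$reads, 99)
  # exactly 100 reads is retained; nothing below: unchanged
  expect_equal(unname(colSums(out$counts)), 101)
  out2 <- filter_samples(out, 100)
  expect_equal(out2$counts, out$counts)
  expect_error(filter_samples(tab, 1e6), "below")
})

test_that("read counts are conserved per sample through clustering", {
  set.seed(28)
  pool <- replicate(8, rand_seq(120))
  seqs <- c(sample(pool, 300, TRUE), replicate(40, rand_seq(120)))
  sid <- sample(c("s1", "s2"), length(seqs), TRUE)
  tab <- dereplicate_and_cluster(merged_set(seqs, sid))
  dt <- table(sid)
  singles_per_sample <- dt - colSums(tab$counts)[names(dt)]
  expect_equal(sum(singles_per_sample), attr(tab, "n_singletons"))
  expect_true(all(singles_per_sample >= 0))
})

test_that("fastq pairs and cluster tables round-trip through disk", {
  set.seed(29)
  tpl <- replicate(3, rand_seq(200))
  p <- read_pairs(substr(tpl, 1, 120), q_str(35, 120),
                  vapply(substr(tpl, 81, 200), rc, character(1)),
                  q_str(35, 120), c("h1", "h1", "h2"))
  d <- withr::local_tempdir()
  write_fastq_pairs(p, d, metadata = data.frame(sample_id = c("h1", "h2"),
                                                year = 2016, month = 5))
  back <- read_fastq_pairs(file.path(d, "samples.tsv"))
  expect_setequal(back$pairs$seq1, p$seq1)
  expect_setequal(back$pairs$seq2, p$seq2)
  expect_equal(back$metadata$year, c(2016, 2016))
  tab <- dereplicate_and_cluster(merged_set(c(tpl[1], tpl[1], tpl[2], tpl[2]),
                                            c("h1", "h2", "h1", "h1")))
  write_cluster_table(tab, d)
  tab2 <- read_cluster_table(d)
  expect_equal(tab2$counts, tab$counts)
  expect_equal(tab2$clusters, tab$clusters)
})
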