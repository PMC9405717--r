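test_that("a query identical to a reference dominates the hit list", {
  set.seed(31)
  tax <- tiny_taxonomy()
  db <- build_reference_database(tax$species_name, tiny_pool(tax, 150), tax)
  q <- db$sequence[db$label == "Rubus fruticosus"]
  hits <- align_and_rank(q, db)
  expect_equal(hits$label[1], "Rubus fruticosus")
  # maximal attainable bitscore for this length: all-match local alignment
  pr <- alignment_params()
  expect_equal(hits$bitscore[1],
               (pr$lambda * pr$match * 150 - log(pr$K)) / log(2))
  expect_equal(hits$identity_pct[1], 100)
  expect_error(align_and_rank("", db), "empty query")
})

test_that("equidistant references score identically and both report", {
  set.seed(32)
  base <- rand_seq(200)
  v1 <- base; substr(v1, 50, 50) <- "A"; substr(v1, 51, 51) <- "C"
  v2 <- base; substr(v2, 50, 50) <- "C"; substr(v2, 51, 51) <- "A"
  q <- base; substr(q, 50, 50) <- "G"; substr(q, 51, 51) <- "G"
  db <- data.frame(record_id = c("x", "y"), label = c("Aa x", "Aa y"),
                   label_rank = "species", sequence = c(v1, v2),
                   stringsAsFactors = FALSE)
  hits <- align_and_rank(q, db)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$bitscore[1], hits$bitscore[2])
})

test_that("local alignment scores match the Biostrings reference", {
  set.seed(33)
  pr <- alignment_params(seed_k = 0)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                 baseOnly = TRUE)
  for (i in 1:20) {
    ref <- rand_seq(180)
    q <- ref
    # substitutions
    for (p in sample(180, 8)) substr(q, p, p) <- sample(c("A","C","G","T"), 1)
    # one short indel, still inside the band
    if (i %% 2 == 0) q <- paste0(substr(q, 1, 90), substr(q, 94, 180))
    db <- data.frame(record_id = "r", label = "Aa x", label_rank = "species",
                     sequence = ref, stringsAsFactors = FALSE)
    hits <- align_and_rank(q, db, params = pr)
    want <- Biostrings::pairwiseAlignment(q, ref, type = "local",
                                          substitutionMatrix = sm,
                                          gapOpening = pr$gap_open,
                                          gapExtension = pr$gap_extend,
                                          scoreOnly = TRUE)
    got <- (hits$bitscore[1] * log(2) + log(pr$K)) / pr$lambda
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("consensus assignment follows the published rule set", {
  tax <- tiny_taxonomy()
  one <- assign_taxon(hitdf("Trifolium repens", "species", 200), tax, "c1")
  expect_equal(one$status, "assigned")
  expect_equal(one$rank, "species")
  expect_equal(one$taxon, "Trifolium repens")

  maleae <- assign_taxon(hitdf(
    c("Crataegus monogyna", "Malus domestica", "Cotoneaster integrifolius"),
    "species", c(180, 180, 180)), tax)
  expect_equal(maleae$rank, "tribe")
  expect_equal(maleae$taxon, "Maleae")

  salix <- assign_taxon(hitdf(c("Salix alba", "Salix caprea"), "species",
                              c(150, 150)), tax)
  expect_equal(salix$rank, "genus")
  expect_equal(salix$taxon, "Salix")

  # same family, no shared tribe -> family; sub-maximal hits do not vote
  fam <- assign_taxon(hitdf(c("Salix alba", "Populus alba", "Rubus fruticosus"),
                            "species", c(150, 150, 120)), tax)
  expect_equal(fam$rank, "family")
  expect_equal(fam$taxon, "Salicaceae")

  # families from different clades: chimeric
  chim <- assign_taxon(hitdf(c("Rubus fruticosus", "Hedera helix"),
                             "species", c(150, 150)), tax)
  expect_equal(chim$status, "chimeric_excluded")

  # several families within one clade: no rule -> unassigned
  amb <- assign_taxon(hitdf(c("Taraxacum officinale", "Hedera helix"),
                            "species", c(150, 150)), tax)
  expect_equal(amb$status, "unassigned")

  # genus-labelled records vote at genus rank, never species
  gen <- assign_taxon(hitdf(c("Rubus fruticosus", "Rubus"),
                            c("species", "genus"), c(150, 150)), tax)
  expect_equal(gen$rank, "genus")
  expect_equal(gen$taxon, "Rubus")

  empty <- assign_taxon(hitdf(character(0), character(0), numeric(0)), tax)
  expect_equal(empty$status, "unassigned")

  expect_error(assign_taxon(hitdf("Nullus nemo", "species", 100), tax),
               "unresolvable")
})

test_that("consensus agrees with the brute-force lineage oracle", {
  set.seed(34)
  for (i in 1:400) {
    tax <- random_toy_taxonomy()
    hits <- random_hitset(tax)
    got <- assign_taxon(hits, tax)
    want <- oracle_assign(hits, tax)
    expect_equal(got$status, want$status)
    if (want$status == "assigned") {
      expect_equal(got$rank, want$rank)
      expect_equal(got$taxon, want$taxon)
    }
  }
})

test_that("splitting a genus never refines an assignment's rank", {
  set.seed(35)
  rank_order <- c(species = 1, genus = 2, tribe = 3, family = 4)
  for (i in 1:60) {
    tax <- random_toy_taxonomy()
    big <- names(which(table(tax$genus) >= 2))
    if (!length(big)) next
    hits <- random_hitset(tax)
    before <- assign_taxon(hits, tax)
    # split one multi-species genus in two (same tribe and family)
    g <- sample(big, 1)
    idx <- which(tax$genus == g)
    movers <- idx[seq_len(ceiling(length(idx) / 2))]
    tax2 <- as.data.frame(tax)
    tax2$genus[movers] <- paste0(g, "bis")
    tax2 <- taxonomy_table(tax2)
    hits2 <- hits[hits$label_rank == "species" | hits$label != g, ,
                  drop = FALSE]
    if (!nrow(hits2)) next
    after <- assign_taxon(hits2, tax2)
    if (before$status == "assigned" && after$status == "assigned" &&
        all(hits$label_rank == "species"))
      expect_gte(rank_order[[after$rank]], rank_order[[before$rank]])
  }
})

test_that("read aggregation sums by taxon and tallies discards", {
  tax <- tiny_taxonomy()
  counts <- matrix(c(5L, 7L, 3L, 2L, 0L, 4L), nrow = 3,
                   dimnames = list(c("c1", "c2", "c3"), c("sA", "sB")))
  tab <- list(clusters = data.frame(cluster_id = c("c1", "c2", "c3"),
                                    representative_sequence = c("A", "C", "G"),
                                    total = c(7L, 5L, 4L)), counts = counts)
  asg <- rbind(
    assign_taxon(hitdf("Rubus", "genus", 100), tax, "c1"),
    assign_taxon(hitdf("Rubus", "genus", 100), tax, "c2"),
    assign_taxon(hitdf(c("Rubus fruticosus", "Hedera helix"), "species",
                       c(90, 90)), tax, "c3"))
  trt <- aggregate_reads(tab, asg)
  expect_equal(unname(trt$counts[, "Rubus"]), c(12, 2))
  expect_equal(trt$discards[["chimeric_excluded"]], 7)
  expect_equal(unname(trt$rank_breakdown["genus"]), 1)
  expect_true(all(rowSums(trt$counts) <= colSums(counts)))
  # all clusters chimeric -> empty table, full discard tally
  chim <- asg[3, ]; chim$cluster_id <- "c1"
  chim2 <- chim; chim2$cluster_id <- "c2"
  chim3 <- chim; chim3$cluster_id <- "c3"
  trt0 <- aggregate_reads(tab, rbind(chim, chim2, chim3))
  expect_equal(ncol(trt0$counts), 0L)
  expect_equal(sum(trt0$discards), sum(counts))
  expect_error(aggregate_reads(tab, asg[-1, ]), "different clusters")
})

test_that("verification flags unsurveyed and out-of-season taxa", {
  tax <- tiny_taxonomy()
  survey <- floral_survey(data.frame(
    zone_id = "z1", year = 2016,
    month = rep(c(5, 6), each = 2),
    species = c("Salix alba", "Crataegus monogyna",
                "Rubus fruticosus", "Crataegus monogyna")), tax)
  counts <- matrix(c(10L, 5L, 2L), nrow = 1,
                   dimnames = list("h1", c("Rubus fruticosus",
                                           "Impatiens glandulifera",
                                           "Salix alba")))
  trt <- structure(list(counts = counts,
                        taxa = data.frame(taxon = colnames(counts),
                                          rank = "species"),
                        discards = c(chimeric_excluded = 0, unassigned = 0),
                        rank_breakdown = c(species = 1, genus = 0, tribe = 0,
                                           family = 0)),
                   class = "taxon_read_table")
  md <- data.frame(sample_id = "h1", year = 2016, month = 6)
  rep <- verification_report(trt, md, survey, tax)
  expect_equal(rep$flag[rep$taxon == "Impatiens glandulifera"],
               "not_in_survey")
  expect_equal(rep$flag[rep$taxon == "Salix alba"], "carryover_candidate")
  expect_false("Rubus fruticosus" %in% rep$taxon)  # in flower: no flag
})
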