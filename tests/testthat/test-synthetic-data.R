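test_that("generation is deterministic given the seed", {
  ds1 <- simulate_dataset(small_config())
  ds2 <- simulate_dataset(small_config())
  expect_identical(ds1$taxonomy, ds2$taxonomy)
  expect_identical(ds1$pool, ds2$pool)
  expect_identical(ds1$pairs, ds2$pairs)
  expect_identical(ds1$ledger$composition, ds2$ledger$composition)
  # different seed: different names, same shape
  ds3 <- simulate_dataset(small_config(seed = 43L))
  expect_false(identical(ds1$taxonomy$species_name,
                         ds3$taxonomy$species_name))
  expect_equal(dim(ds3$taxonomy), dim(ds1$taxonomy))
  expect_equal(length(unique(ds3$taxonomy$clade)),
               length(unique(ds1$taxonomy$clade)))
})

test_that("the taxonomy has the configured shape and resolves lineages", {
  cfg <- small_config()
  tax <- make_taxonomy(cfg)
  expect_equal(nrow(tax), cfg$n_species)
  expect_equal(length(unique(tax$genus)), cfg$n_genera)
  expect_equal(length(unique(tax$family)), cfg$n_families)
  expect_equal(length(unique(tax$clade)), cfg$n_clades)
  lin <- resolve_labels(tax, tax$species_name[1:5], "species")
  expect_false(anyNA(lin$clade))
  expect_error(generator_config(n_species = 3, n_genera = 10), "species >=")
})

test_that("reference coverage tracks the configured fraction", {
  cfg <- small_config(ref_species_coverage = 1, n_orphan_species = 0L,
                      twin_pair = FALSE)
  tax <- make_taxonomy(cfg)
  rp <- make_reference_pool(tax, cfg)
  db <- build_reference_database(tax$species_name, rp$pool, tax)
  cov <- coverage_stats(db, tax$species_name, tax)
  expect_equal(cov$species_pct, 100)
  expect_equal(cov$genus_pct, 100)

  cfg2 <- small_config(ref_species_coverage = 0.5)
  tax2 <- make_taxonomy(cfg2)
  rp2 <- make_reference_pool(tax2, cfg2)
  db2 <- build_reference_database(tax2$species_name, rp2$pool, tax2)
  cov2 <- coverage_stats(db2, tax2$species_name, tax2)
  expect_equal(cov2$species_pct, 50, tolerance = 0.1)
  expect_gte(cov2$genus_pct, cov2$species_pct)
  expect_lt(cov2$genus_pct, 100)  # orphan genera stay unreferenced
  # generator coverage map agrees with the database-derived statistics
  expect_equal(mean(rp2$coverage$species_covered) * 100, cov2$species_pct)
  expect_equal(mean(rp2$coverage$genus_covered) * 100, cov2$genus_pct)
})

test_that("sequence-identical twins force genus-rank assignments", {
  cfg <- small_config()
  tax <- make_taxonomy(cfg)
  rp <- make_reference_pool(tax, cfg)
  twins <- rp$special$twins
  db <- build_reference_database(tax$species_name, rp$pool, tax)
  hits <- align_and_rank(rp$amplicons[[twins[1]]], db)
  asg <- assign_taxon(hits, tax)
  expect_equal(asg$rank, "genus")
  expect_equal(asg$taxon, tax$genus[tax$species_name == twins[1]])
})

test_that("the survey covers scheduled forage except the planted invader", {
  ds <- simulate_dataset(small_config())
  inv <- ds$ledger$special$invader
  surveyed <- unique(ds$survey$species[!is.na(ds$survey$species)])
  used <- unique(ds$ledger$composition$taxon[ds$ledger$composition$base_p > 0])
  expect_false(inv %in% surveyed)
  expect_true(inv %in% used)
  carry <- ds$ledger$special$carryover
  # the carryover plant flowers only in August-September
  w <- ds$windows[ds$windows$species == carry, ]
  expect_equal(c(w$from, w$to), c(8L, 9L))
  # and holds about 5% of scheduled April-2017 reads
  apr <- ds$schedule[["2017-04"]]
  expect_gt(apr[[carry]], 0.04)
  # everything else scheduled in a month is in flower that month
  for (key in names(ds$schedule)) {
    m <- as.integer(sub(".*-", "", key))
    sched <- setdiff(names(ds$schedule[[key]]), c(inv, carry))
    w <- ds$windows[match(sched, ds$windows$species), ]
    expect_true(all(w$from <= m & w$to >= m))
  }
})

test_that("every forage band is planted in the default schedule", {
  ds <- simulate_dataset(small_config())
  bands <- unlist(lapply(ds$schedule, function(b)
    as.character(categorize_rra(b))))
  expect_setequal(intersect(bands, c("major", "secondary", "minor",
                                     "occasional")),
                  c("major", "secondary", "minor", "occasional"))
})

test_that("singleton noise injections never survive clustering", {
  cfg <- small_config(substitution_rate = 0, chimera_rate = 0,
                      singleton_rate = 0.05)
  ds <- simulate_dataset(cfg)
  proc <- process_reads(ds$pairs, filter = list(min_reads = 1L))
  n_noise <- sum(ds$ledger$noise$n_reads)
  expect_gt(n_noise, 0)
  # every surviving representative is a known amplicon, never a noise read
  expect_true(all(proc$table$clusters$representative_sequence %in%
                    ds$amplicons))
})

test_that("noiseless generation recovers truth exactly after classification", {
  cfg <- small_config(substitution_rate = 0, chimera_rate = 0,
                      singleton_rate = 0, ref_species_coverage = 1,
                      n_orphan_species = 0L, twin_pair = FALSE)
  ds <- simulate_dataset(cfg)
  pl <- run_pipeline(ds)
  expect_true(all(pl$assignments$status == "assigned"))
  expect_true(all(pl$assignments$rank == "species"))
  truth <- truth_monthly_rra(ds$ledger, ds$taxonomy, "species")
  truth <- truth[truth$rra > 0, , drop = FALSE]
  got <- monthly_rra(pl$taxon_table, ds$metadata)
  for (i in seq_len(nrow(truth))) {
    g <- got$rra[got$year == truth$year[i] & got$month == truth$month[i] &
                   got$taxon == truth$taxon[i]]
    expect_equal(g, truth$rra[i], tolerance = 1e-12)
  }
})

test_that("chimera injections at the planted rate appear in the ledger", {
  cfg <- small_config(chimera_rate = 0.1)
  ds <- simulate_dataset(cfg)
  n_chim <- sum(ds$ledger$chimeras$N)
  n_total <- length(ds$pairs$seq1)
  expect_equal(n_chim / n_total, 0.1, tolerance = 0.02)
  # chimeras splice two distinct parents at the recorded breakpoint
  ch <- ds$ledger$chimeras[1, ]
  expect_false(ch$parent1 == ch$parent2)
  built <- paste0(substr(ds$amplicons[[ch$parent1]], 1, ch$breakpoint),
                  substr(ds$amplicons[[ch$parent2]], ch$breakpoint + 1,
                         nchar(ds$amplicons[[ch$parent2]])))
  expect_true(built %in% ds$pairs$seq1 |
                substr(built, 1, cfg$read_len) %in% ds$pairs$seq1)
})

test_that("short-amplicon taxa are flagged unretained in the ledger", {
  ds <- simulate_dataset(small_config())
  short_sp <- ds$ledger$special$short_species
  comp <- ds$ledger$composition
  expect_true(all(!comp$retained[comp$taxon %in% short_sp]))
  expect_true(all(comp$retained[!comp$taxon %in% short_sp]))
  # merged output drops exactly the short-amplicon reads
  trimmed <- quality_trim(ds$pairs)
  merged <- merge_pairs(trimmed)
  lost <- length(trimmed$seq1) - length(merged$sequence)
  planted_short <- sum(comp$n_reads[!comp$retained])
  # chimeras inherit their 3' parent's length, so short 3' parents also fail
  chim_short <- sum(ds$ledger$chimeras$N[
    ds$ledger$chimeras$parent2 %in% short_sp])
  expect_equal(lost, planted_short + chim_short)
})
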