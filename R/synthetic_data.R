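#' Configuration for the synthetic honey-metabarcoding scenario
#'
#' Defaults emulate the study design the pipeline targets: two apiaries of
#' three hives sampled monthly from April to September over two years (the
#' first April unsampled, 11 months, 66 samples), a small plant taxonomy
#' spanning several clades, a reference pool with incomplete species-level
#' coverage (57% of the species list), amplicons of about 500 bp read as
#' 2 x 300 bp pairs, low-rate substitution errors, cross-taxon chimeras and
#' unique singleton noise, and a matching floral survey. Seasonal
#' compositions are tiered so that every forage-category band
#' (major/secondary/minor/occasional) is planted, with one out-of-season
#' "carryover" taxon, one never-surveyed "invader", a twin pair of
#' sequence-identical species (forcing genus-level calls) and one
#' short-amplicon taxon whose merged reads fail the 450 bp filter.
#'
#' @param seed integer seed driving every random choice.
#' @param n_clades,n_families,n_genera,n_species taxonomy dimensions
#'   (species >= genera >= families >= clades).
#' @param ref_species_coverage fraction of the species list with
#'   species-rank reference records.
#' @param n_orphan_species species whose genus has no reference record at
#'   all (genus-level coverage gap).
#' @param amplicon_len,short_amplicon_len,read_len sequence lengths (bp).
#' @param genus_divergence per-base divergence of species sequences from
#'   their genus base sequence (and of the genus-rank record).
#' @param months data.frame `year`, `month` of sampled months.
#' @param n_samples_per_month hives sampled per month.
#' @param reads_per_sample read pairs generated per sample.
#' @param substitution_rate,chimera_rate,singleton_rate per-read error,
#'   chimera and unique-noise rates.
#' @param concentration Dirichlet concentration of per-sample compositions
#'   around the monthly schedule.
#' @param lowq_tail_frac,tail_len,base_q,tail_q quality model: fraction of
#'   second mates given a low-quality 3' tail, its length, and the Phred
#'   scores of good bases and tail bases.
#' @param n_zones survey zones.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_clades = 3L, n_families = 6L, n_genera = 15L,
                             n_species = 40L,
                             ref_species_coverage = 0.57,
                             n_orphan_species = 2L,
                             twin_pair = TRUE,
                             amplicon_len = 500L, short_amplicon_len = 430L,
                             read_len = 300L,
                             genus_divergence = 0.02,
                             months = study_months(),
                             n_samples_per_month = 6L,
                             reads_per_sample = 20000L,
                             substitution_rate = 0.002,
                             chimera_rate = 0.02,
                             singleton_rate = 0.01,
                             concentration = 300,
                             lowq_tail_frac = 0.05, tail_len = 50L,
                             base_q = 37L, tail_q = 10L,
                             n_zones = 3L) {
  cfg <- as.list(environment())
  rates <- c(cfg$ref_species_coverage, cfg$substitution_rate,
             cfg$chimera_rate, cfg$singleton_rate, cfg$lowq_tail_frac)
  if (any(rates < 0 | rates > 1)) stop_hf("rates must lie in [0, 1]")
  if (!(n_species >= n_genera && n_genera >= n_families &&
        n_families >= n_clades && n_clades >= 2L))
    stop_hf("need species >= genera >= families >= clades >= 2")
  class(cfg) <- "generator_config"
  cfg
}

#' @rdname generator_config
#' @export
study_months <- function() {
  data.frame(year = c(rep(2016L, 5), rep(2017L, 6)),
             month = c(5:9, 4:9))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

syllables <- c("al", "be", "cor", "da", "el", "fi", "ga", "hi", "ju", "ka",
               "lo", "mi", "no", "or", "pu", "ra", "si", "tu", "ve", "zo")

make_names <- function(n, n_syll = 3L, capitalize = TRUE) {
  out <- character(0)
  while (length(out) < n) {
    nm <- paste(sample(syllables, n_syll, replace = TRUE), collapse = "")
    if (capitalize)
      nm <- paste0(toupper(substr(nm, 1, 1)), substr(nm, 2, nchar(nm)))
    out <- unique(c(out, nm))
  }
  out[seq_len(n)]
}

#' Generate a synthetic plant taxonomy
#'
#' A balanced-ish random hierarchy with pronounceable pseudo-Latin names:
#' genera spread over families, families over at least two clades (so
#' cross-clade chimeras exist), and one multi-genus tribe inside the first
#' family (a Maleae-like group). The last genera are single-species, so
#' orphan (wholly unreferenced) genera can be planted there. Deterministic
#' given the config seed.
#'
#' @param config a [generator_config()].
#' @return a [taxonomy_table()].
#' @export
make_taxonomy <- function(config) {
  with_seed(config$seed + 101L, {
    ng <- config$n_genera; nf <- config$n_families; nc <- config$n_clades
    genera <- make_names(ng, 3L)
    families <- paste0(make_names(nf, 2L), "aceae")
    clades <- paste0(make_names(nc, 2L), "ids")
    fam_of_gen <- rep(seq_len(nf), length.out = ng)
    clade_of_fam <- rep(seq_len(nc), length.out = nf)
    # species per genus: every genus >= 1; first genera are speciose,
    # the last two are single-species (orphan slots)
    extra <- config$n_species - ng
    gets_extra <- rep(seq_len(max(1L, ng - 2L)), length.out = extra)
    n_sp <- tabulate(gets_extra, nbins = ng) + 1L
    tribe_name <- paste0(make_names(1L, 2L), "eae")
    rows <- list()
    for (g in seq_len(ng)) {
      eps <- make_names(n_sp[g] + 2L, 2L, capitalize = FALSE)
      eps <- setdiff(eps, "")[seq_len(n_sp[g])]
      fam <- families[fam_of_gen[g]]
      rows[[g]] <- data.frame(
        species_name = paste(genera[g], eps),
        genus = genera[g],
        tribe = if (fam_of_gen[g] == 1L) tribe_name else NA_character_,
        family = fam,
        clade = clades[clade_of_fam[fam_of_gen[g]]],
        stringsAsFactors = FALSE)
    }
    taxonomy_table(do.call(rbind, rows))
  })
}

mutate_fixed <- function(seq, n_mut) {
  if (n_mut <= 0) return(seq)
  bases <- c("A", "C", "G", "T")
  s <- strsplit(seq, "")[[1]]
  pos <- sample(length(s), n_mut)
  for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
  paste(s, collapse = "")
}

#' Generate the reference pool and coverage map
#'
#' One random base sequence per genus; species amplicons diverge from their
#' genus base at a fixed per-base rate, except a designated twin pair that
#' shares one sequence, and one short-amplicon genus whose amplicon fails
#' the merged-length filter downstream. A seed-chosen fraction of species
#' receives species-rank records; genera containing uncovered species
#' receive a genus-rank record (the genus base itself), except the orphan
#' genera, which get none.
#'
#' @param taxonomy a [make_taxonomy()] result.
#' @param config a [generator_config()].
#' @return list: `pool` (reference records), `amplicons` (named per-species
#'   sequences), `coverage` (data.frame species/species_covered/
#'   genus_covered), `special` (named special taxa).
#' @export
make_reference_pool <- function(taxonomy, config) {
  with_seed(config$seed + 202L, {
    genera <- unique(taxonomy$genus)
    ng <- length(genera)
    # the last single-species genera host the orphans; the one before the
    # orphans hosts the short amplicon
    orphan_gen <- tail(genera, config$n_orphan_species)
    short_gen <- genera[ng - config$n_orphan_species]
    glen <- setNames(rep(config$amplicon_len, ng), genera)
    glen[short_gen] <- config$short_amplicon_len
    gbase <- setNames(vapply(genera, function(g)
      as.character(random_seqs_cpp(1L, glen[[g]])), character(1)), genera)
    n_mut <- round(config$genus_divergence * config$amplicon_len)
    sp <- taxonomy$species_name
    amplicons <- setNames(vapply(seq_along(sp), function(i) {
      mutate_fixed(gbase[[taxonomy$genus[i]]], n_mut)
    }, character(1)), sp)
    while (anyDuplicated(amplicons)) {   # congeners must stay distinguishable
      i <- which(duplicated(amplicons))[1]
      amplicons[i] <- mutate_fixed(gbase[[taxonomy$genus[i]]], n_mut)
    }
    twins <- character(0)
    if (isTRUE(config$twin_pair)) {
      # twin pair: two congeners sharing one sequence (first genus with >= 2)
      twin_gen <- genera[which(table(taxonomy$genus)[genera] >= 2)[1]]
      twins <- sp[taxonomy$genus == twin_gen][1:2]
      amplicons[twins[2]] <- amplicons[twins[1]]
    }
    orphans <- sp[taxonomy$genus %in% orphan_gen]
    eligible <- setdiff(sp, orphans)
    n_cov <- round(config$ref_species_coverage * length(sp))
    forced <- unique(c(twins, sp[taxonomy$genus == short_gen]))
    free <- setdiff(eligible, forced)
    covered <- unique(c(forced,
                        sample(free, min(length(free),
                                         max(0L, n_cov - length(forced))))))
    uncovered <- setdiff(sp, covered)
    fallback_gen <- setdiff(unique(
      taxonomy$genus[match(uncovered, taxonomy$species_name)]), orphan_gen)
    pool <- data.frame(
      record_id = paste0("SP", sprintf("%03d", match(covered, sp))),
      label = covered, label_rank = rep("species", length(covered)),
      sequence = unname(amplicons[covered]), stringsAsFactors = FALSE)
    if (length(fallback_gen))
      pool <- rbind(pool, data.frame(
        record_id = paste0("GN", sprintf("%03d", match(fallback_gen, genera))),
        label = fallback_gen, label_rank = "genus",
        sequence = unname(gbase[fallback_gen]), stringsAsFactors = FALSE))
    gen_of <- taxonomy$genus[match(sp, taxonomy$species_name)]
    coverage <- data.frame(
      species = sp,
      species_covered = sp %in% covered,
      genus_covered = gen_of %in% c(gen_of[sp %in% covered], fallback_gen),
      stringsAsFactors = FALSE)
    list(pool = validate_pool(pool), amplicons = amplicons,
         coverage = coverage,
         special = list(twins = twins, orphans = orphans,
                        short_species = sp[taxonomy$genus == short_gen],
                        short_genus = short_gen))
  })
}

#' Generate flowering windows, floral survey, traits and monthly schedule
#'
#' Growth form follows the genus (early genera are trees, then shrubs, then
#' herbs) and flowering windows follow form: trees peak early in the season
#' (April-May), shrubs mid-season, herbs mid-to-late, so trees dominate the
#' early forage. The survey lists, per zone and month, the species in
#' flower (windows minus the invader). The monthly composition schedule
#' assigns tiered base proportions exercising every forage band, plants a
#' carryover taxon (5% of April-2017 reads from an autumn flowerer) and a
#' never-surveyed invader in August-September.
#'
#' @param taxonomy a [make_taxonomy()] result.
#' @param config a [generator_config()].
#' @param refpool result of [make_reference_pool()] (coverage steers which
#'   taxa can be scheduled as major/secondary forage).
#' @return list: `survey` (a [floral_survey()]), `traits` (a
#'   [trait_table()] covering all species, genera and tribes), `windows`
#'   (species flowering windows), `schedule` (per year-month named base
#'   proportions), `special` (carryover/invader taxa).
#' @export
make_survey_and_traits <- function(taxonomy, config, refpool) {
  with_seed(config$seed + 303L, {
    sp <- taxonomy$species_name
    genera <- unique(taxonomy$genus)
    ng <- length(genera)
    form_of_gen <- setNames(
      rep(c("tree", "shrub", "herb"),
          c(ceiling(ng / 4), ceiling(ng / 3),
            ng - ceiling(ng / 4) - ceiling(ng / 3))), genera)
    gen_of <- taxonomy$genus[match(sp, taxonomy$species_name)]
    form <- unname(form_of_gen[gen_of])
    peak <- ifelse(form == "tree", sample(4:5, length(sp), TRUE),
            ifelse(form == "shrub", sample(5:7, length(sp), TRUE),
                   sample(6:9, length(sp), TRUE)))
    windows <- data.frame(species = sp,
                          from = pmax(4L, peak - 1L),
                          to = pmin(9L, peak + 1L),
                          stringsAsFactors = FALSE)
    # carryover plant: an autumn-only herb; invader: never surveyed
    herbs <- sp[form == "herb" & refpool$coverage$genus_covered &
                  !sp %in% refpool$special$short_species]
    carryover <- herbs[1]
    invader <- herbs[2]
    windows$from[windows$species == carryover] <- 8L
    windows$to[windows$species == carryover] <- 9L
    windows$from[windows$species == invader] <- NA_integer_
    windows$to[windows$species == invader] <- NA_integer_

    status <- ifelse(sp == invader, "naturalized",
                     ifelse(seq_along(sp) %% 4 == 0, "horticultural",
                            "native_or_near_native"))
    habitat <- ifelse(form == "tree", "broadleaved_woodland",
               ifelse(form == "shrub", "hedgerow_linear",
                      ifelse(seq_along(sp) %% 3 == 0, "garden", "grassland")))
    traits_sp <- data.frame(taxon = sp, rank = "species", status = status,
                            form = form, habitat = habitat,
                            stringsAsFactors = FALSE)
    maj_level <- function(x) names(sort(table(x), decreasing = TRUE))[1]
    traits_gen <- do.call(rbind, lapply(genera, function(g) {
      i <- gen_of == g
      data.frame(taxon = g, rank = "genus",
                 status = maj_level(status[i]), form = form_of_gen[[g]],
                 habitat = maj_level(habitat[i]), stringsAsFactors = FALSE)
    }))
    tribes <- unique(taxonomy$tribe[!is.na(taxonomy$tribe)])
    traits_tr <- do.call(rbind, lapply(tribes, function(tr) {
      i <- !is.na(taxonomy$tribe) & taxonomy$tribe == tr
      i <- sp %in% taxonomy$species_name[i]
      data.frame(taxon = tr, rank = "tribe",
                 status = maj_level(status[i]), form = maj_level(form[i]),
                 habitat = maj_level(habitat[i]), stringsAsFactors = FALSE)
    }))
    traits <- trait_table(rbind(traits_sp, traits_gen, traits_tr))

    # survey: zones cycle over species; a third of species appear in two zones
    months <- config$months
    obs <- list()
    for (i in seq_len(nrow(months))) {
      m <- months$month[i]
      inflower <- windows$species[!is.na(windows$from) &
                                    windows$from <= m & windows$to >= m]
      if (!length(inflower)) next
      zone <- (match(inflower, sp) %% config$n_zones) + 1L
      obs[[length(obs) + 1L]] <- data.frame(
        zone_id = paste0("zone", zone), year = months$year[i], month = m,
        species = inflower, stringsAsFactors = FALSE)
      dup <- inflower[match(inflower, sp) %% 3L == 0L]
      if (length(dup))
        obs[[length(obs) + 1L]] <- data.frame(
          zone_id = paste0("zone", ((match(dup, sp) + 1L) %% config$n_zones) + 1L),
          year = months$year[i], month = m, species = dup,
          stringsAsFactors = FALSE)
    }
    survey <- floral_survey(unique(do.call(rbind, obs)), taxonomy)

    # tiered monthly base compositions (shared across years per month)
    tiers <- c(0.30, 0.20, 0.05, 0.03, 0.02, 0.005, 0.002, 5e-5)
    month_order <- lapply(4:9, function(m) {
      inflower <- windows$species[!is.na(windows$from) &
                                    windows$from <= m & windows$to >= m]
      covered <- inflower[refpool$coverage$genus_covered[
        match(inflower, refpool$coverage$species)]]
      rest <- setdiff(inflower, covered)
      c(sample(covered), sample(rest))
    })
    names(month_order) <- as.character(4:9)
    schedule <- list()
    for (i in seq_len(nrow(months))) {
      y <- months$year[i]; m <- months$month[i]
      ord <- month_order[[as.character(m)]]
      base <- setNames(tiers[seq_len(min(length(ord), length(tiers)))],
                       ord[seq_len(min(length(ord), length(tiers)))])
      if (y == 2017L && m == 4L) {
        extra <- setNames(0.05, carryover)
        base <- c(base, extra)
      }
      if (m >= 8L) base <- c(base, setNames(0.05, invader))
      base <- base / sum(base)
      schedule[[sprintf("%d-%02d", y, m)]] <- base
    }
    list(survey = survey, traits = traits, windows = windows,
         schedule = schedule,
         special = list(carryover = carryover, invader = invader))
  })
}

#' Simulate paired amplicon reads with a truth ledger
#'
#' Per sample: true taxon proportions are drawn from a Dirichlet around the
#' monthly schedule; genuine reads copy the taxon amplicon with per-base
#' substitution errors; chimeric reads splice two active amplicons at one of
#' five fixed relative breakpoints (so identical chimeras recur and survive
#' singleton removal); singleton noise reads are unique random sequences.
#' Amplicons are emitted as 2 x `read_len` pairs overlapping in the middle,
#' read 2 receiving a low-quality 3' tail with probability
#' `lowq_tail_frac`.
#'
#' @param taxonomy,config,refpool,scenery results of the other generator
#'   steps (`scenery` from [make_survey_and_traits()]).
#' @return list: `pairs` (a `read_pairs`), `metadata` (sample sheet),
#'   `ledger` (truth ledger, see Details).
#' @details The ledger aggregates per-read provenance by (sample, kind,
#'   taxon): `composition` holds drawn proportions and realized genuine read
#'   counts (with a `retained` flag that is FALSE for short-amplicon taxa
#'   removed by the merged-length filter), `chimeras` the spliced pairs with
#'   breakpoints and counts, `noise` the singleton injections, plus the
#'   coverage map, flowering windows and special taxa.
#' @export
simulate_reads <- function(taxonomy, config, refpool, scenery) {
  with_seed(config$seed + 404L, {
    months <- config$months
    amplicons <- refpool$amplicons
    alen <- nchar(amplicons)
    retained_taxon <- alen >= 450L
    comp <- list(); chim <- list(); noise <- list()
    seqs_all <- list(); sid_all <- list()
    meta <- list()
    for (i in seq_len(nrow(months))) {
      y <- months$year[i]; m <- months$month[i]
      base <- scenery$schedule[[sprintf("%d-%02d", y, m)]]
      for (h in seq_len(config$n_samples_per_month)) {
        sid <- sprintf("s%d_%02d_h%d", y, m, h)
        meta[[length(meta) + 1L]] <- data.frame(
          sample_id = sid, year = y, month = m,
          apiary = ifelse(h <= 3, "A", "B"), hive = h,
          stringsAsFactors = FALSE)
        a <- rgamma(length(base), shape = config$concentration * base)
        p <- if (sum(a) > 0) a / sum(a) else base
        n <- config$reads_per_sample
        n_chim <- rbinom(1L, n, config$chimera_rate)
        n_noise <- rbinom(1L, n, config$singleton_rate)
        n_gen <- n - n_chim - n_noise
        cnt <- as.integer(rmultinom(1L, n_gen, p))
        comp[[length(comp) + 1L]] <- data.frame(
          sample_id = sid, year = y, month = m, taxon = names(base),
          base_p = unname(base), drawn_p = unname(p), n_reads = cnt,
          retained = retained_taxon[names(base)], stringsAsFactors = FALSE)
        gen_seqs <- rep(unname(amplicons[names(base)]), cnt)
        if (config$substitution_rate > 0)
          gen_seqs <- as.character(mutate_seqs_cpp(gen_seqs,
                                                   config$substitution_rate))
        chim_seqs <- character(0)
        if (n_chim > 0) {
          act <- names(base)[base > 0.001]
          pa <- sample(act, n_chim, TRUE, prob = base[act])
          pb <- vapply(pa, function(x) sample(setdiff(act, x), 1L),
                       character(1))
          frac <- sample(c(0.3, 0.4, 0.5, 0.6, 0.7), n_chim, TRUE)
          k <- floor(frac * pmin(alen[pa], alen[pb]))
          chim_seqs <- paste0(substr(amplicons[pa], 1L, k),
                              substr(amplicons[pb], k + 1L, alen[pb]))
          cdt <- data.table::data.table(sample_id = sid, parent1 = pa,
                                        parent2 = pb, breakpoint = k)
          chim[[length(chim) + 1L]] <-
            as.data.frame(cdt[, .N, by = .(sample_id, parent1, parent2,
                                           breakpoint)])
        }
        noise_seqs <- if (n_noise > 0)
          as.character(random_seqs_cpp(n_noise, config$amplicon_len)) else
          character(0)
        noise[[length(noise) + 1L]] <- data.frame(
          sample_id = sid, n_reads = n_noise, stringsAsFactors = FALSE)
        seqs <- c(gen_seqs, chim_seqs, noise_seqs)
        seqs_all[[length(seqs_all) + 1L]] <- seqs
        sid_all[[length(sid_all) + 1L]] <- rep(sid, length(seqs))
      }
    }
    seqs <- unlist(seqs_all, use.names = FALSE)
    sid <- unlist(sid_all, use.names = FALSE)
    L <- nchar(seqs)
    r1 <- substr(seqs, 1L, config$read_len)
    r2 <- as.character(revcomp_cpp(substr(seqs, L - config$read_len + 1L, L)))
    qgood <- strrep(rawToChar(as.raw(config$base_q + 33L)), config$read_len)
    qtail <- paste0(
      strrep(rawToChar(as.raw(config$base_q + 33L)),
             config$read_len - config$tail_len),
      strrep(rawToChar(as.raw(config$tail_q + 33L)), config$tail_len))
    q1 <- rep(qgood, length(seqs))
    q2 <- ifelse(runif(length(seqs)) < config$lowq_tail_frac, qtail, qgood)
    pairs <- read_pairs(r1, q1, r2, q2, sid)
    ledger <- list(
      composition = do.call(rbind, comp),
      chimeras = if (length(chim)) do.call(rbind, chim) else
        data.frame(sample_id = character(), parent1 = character(),
                   parent2 = character(), breakpoint = integer(),
                   N = integer()),
      noise = do.call(rbind, noise),
      coverage = refpool$coverage,
      windows = scenery$windows,
      special = c(refpool$special, scenery$special))
    list(pairs = pairs, metadata = do.call(rbind, meta), ledger = ledger)
  })
}

#' Generate the complete synthetic dataset
#'
#' Runs all generator stages and bundles every pipeline input with the truth
#' ledger. Byte-identical across reruns with the same config.
#'
#' @param config a [generator_config()].
#' @return list: `taxonomy`, `species_list`, `pool`, `amplicons`, `survey`,
#'   `traits`, `windows`, `schedule`, `pairs`, `metadata`, `ledger`.
#' @export
simulate_dataset <- function(config = generator_config()) {
  taxonomy <- make_taxonomy(config)
  refpool <- make_reference_pool(taxonomy, config)
  scenery <- make_survey_and_traits(taxonomy, config, refpool)
  reads <- simulate_reads(taxonomy, config, refpool, scenery)
  list(taxonomy = taxonomy,
       species_list = species_list(taxonomy$species_name, taxonomy),
       pool = refpool$pool, amplicons = refpool$amplicons,
       survey = scenery$survey, traits = scenery$traits,
       windows = scenery$windows, schedule = scenery$schedule,
       pairs = reads$pairs, metadata = reads$metadata,
       ledger = reads$ledger, config = config)
}

#' Ground-truth monthly relative read abundance from the ledger
#'
#' Pools the realized genuine read counts of retained (length-passing) taxa
#' by month and converts them to proportions, at species level or aggregated
#' to genus level — the reference against which pipeline recovery is judged.
#'
#' @param ledger truth ledger from [simulate_reads()].
#' @param taxonomy the matching taxonomy (needed for `level = "genus"`).
#' @param level `"species"` or `"genus"`.
#' @return data.frame: `year`, `month`, `taxon`, `rra`.
#' @export
truth_monthly_rra <- function(ledger, taxonomy = NULL,
                              level = c("species", "genus")) {
  level <- match.arg(level)
  comp <- ledger$composition[ledger$composition$retained, , drop = FALSE]
  tax <- if (level == "genus")
    taxonomy$genus[match(comp$taxon, taxonomy$species_name)] else comp$taxon
  dt <- data.table::data.table(year = comp$year, month = comp$month,
                               taxon = tax, n = comp$n_reads)
  agg <- dt[, .(n = sum(n)), by = .(year, month, taxon)]
  agg[, rra := n / sum(n), by = .(year, month)]
  out <- as.data.frame(agg[order(year, month, -rra)])
  out$n <- NULL
  out
}

#' Run the full pipeline on a synthetic (or equivalent) dataset
#'
#' Convenience end-to-end driver: builds the reference database, processes
#' reads, classifies clusters and aggregates the taxon read table.
#'
#' @param dataset list as returned by [simulate_dataset()].
#' @param min_merged_len,min_sample_reads filters forwarded to the
#'   read-processing stage.
#' @param top_n,params classifier settings.
#' @return list: `refdb`, `coverage`, `table` (cluster table), `log`,
#'   `assignments`, `taxon_table`.
#' @export
run_pipeline <- function(dataset, min_merged_len = 450L,
                         min_sample_reads = 100L, top_n = 20L,
                         params = alignment_params()) {
  refdb <- build_reference_database(dataset$species_list, dataset$pool,
                                    dataset$taxonomy)
  cov <- coverage_stats(refdb, dataset$species_list, dataset$taxonomy)
  proc <- process_reads(dataset$pairs,
                        merge = list(min_merged_len = min_merged_len),
                        filter = list(min_reads = min_sample_reads))
  assignments <- classify_clusters(proc$table, refdb, dataset$taxonomy,
                                   top_n = top_n, params = params)
  trt <- aggregate_reads(proc$table, assignments)
  list(refdb = refdb, coverage = cov, table = proc$table, log = proc$log,
       assignments = assignments, taxon_table = trt)
}
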