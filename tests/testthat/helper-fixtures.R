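# Shared fixtures: a small hand-written taxonomy with familiar forage plants,
# sequence helpers, and independent oracles used to cross-check the
# implementation (brute-force consensus assignment, R-side window trimming).

tiny_taxonomy <- function() {
  taxonomy_table(data.frame(
    species_name = c("Crataegus monogyna", "Malus domestica",
                     "Cotoneaster integrifolius", "Rubus fruticosus",
                     "Rosa canina", "Salix alba", "Salix caprea",
                     "Populus alba", "Trifolium repens", "Ulex europaeus",
                     "Taraxacum officinale", "Cirsium arvense",
                     "Hedera helix", "Impatiens glandulifera"),
    genus = c("Crataegus", "Malus", "Cotoneaster", "Rubus", "Rosa", "Salix",
              "Salix", "Populus", "Trifolium", "Ulex", "Taraxacum",
              "Cirsium", "Hedera", "Impatiens"),
    tribe = c("Maleae", "Maleae", "Maleae", "Rubeae", "Roseae", NA, NA, NA,
              "Trifolieae", "Genisteae", NA, NA, NA, NA),
    family = c("Rosaceae", "Rosaceae", "Rosaceae", "Rosaceae", "Rosaceae",
               "Salicaceae", "Salicaceae", "Salicaceae", "Fabaceae",
               "Fabaceae", "Asteraceae", "Asteraceae", "Araliaceae",
               "Balsaminaceae"),
    clade = c(rep("rosids", 10), "asterids", "asterids", "asterids",
              "asterids"),
    stringsAsFactors = FALSE))
}

rand_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE),
                                collapse = "")

rc <- function(s) as.character(Biostrings::reverseComplement(
  Biostrings::DNAStringSet(s)))

# one random species-rank reference record per taxonomy species
tiny_pool <- function(taxonomy, len = 120L) {
  data.frame(record_id = sprintf("R%03d", seq_len(nrow(taxonomy))),
             label = taxonomy$species_name, label_rank = "species",
             sequence = vapply(seq_len(nrow(taxonomy)),
                               function(i) rand_seq(len), character(1)),
             stringsAsFactors = FALSE)
}

hitdf <- function(labels, ranks, bitscores,
                  ids = sprintf("H%02d", seq_along(labels))) {
  data.frame(record_id = ids, label = labels,
             label_rank = rep_len(ranks, length(labels)),
             bitscore = bitscores,
             identity_pct = rep_len(100, length(labels)),
             stringsAsFactors = FALSE)[order(-bitscores), , drop = FALSE]
}

# split a template into an overlapping 2 x read_len pair with flat qualities
template_pair <- function(template, read_len, sample_id = "s1", q = 37L) {
  L <- nchar(template)
  stopifnot(L >= read_len)
  qs <- strrep(rawToChar(as.raw(q + 33L)), read_len)
  read_pairs(substr(template, 1L, read_len), qs,
             rc(substr(template, L - read_len + 1L, L)), qs, sample_id)
}

merged_set <- function(seqs, sample_ids) {
  structure(list(sequence = seqs, sample_id = sample_ids),
            class = "merged_reads")
}

# independent brute-force consensus: exhaustive lineage intersection of the
# max-bitscore set, walked bottom-up rank by rank
oracle_assign <- function(hits, taxonomy, tol = 1e-9) {
  if (is.null(hits) || !nrow(hits))
    return(list(status = "unassigned", rank = NA_character_,
                taxon = NA_character_))
  top <- hits[hits$bitscore >= max(hits$bitscore) * (1 - tol), , drop = FALSE]
  tax <- as.data.frame(taxonomy)
  path_of <- function(label, rank) {
    if (rank == "species") {
      r <- tax[tax$species_name == label, , drop = FALSE]
      list(species = label, genus = r$genus, tribe = r$tribe,
           family = r$family, clade = r$clade)
    } else {
      r <- tax[tax$genus == label, , drop = FALSE]
      tr <- unique(r$tribe)
      list(species = NA_character_, genus = label,
           tribe = if (length(tr) == 1L) tr else NA_character_,
           family = unique(r$family), clade = unique(r$clade))
    }
  }
  paths <- mapply(path_of, top$label, top$label_rank, SIMPLIFY = FALSE)
  for (rank in c("species", "genus", "tribe", "family")) {
    vals <- vapply(paths, function(p) p[[rank]][1], character(1))
    if (!anyNA(vals) && length(unique(vals)) == 1L)
      return(list(status = "assigned", rank = rank, taxon = unique(vals)))
  }
  clades <- unique(vapply(paths, function(p) p$clade[1], character(1)))
  if (length(clades) == 1L)
    list(status = "unassigned", rank = NA_character_, taxon = NA_character_)
  else
    list(status = "chimeric_excluded", rank = NA_character_,
         taxon = NA_character_)
}

# random toy taxonomy for property tests over the consensus rule
random_toy_taxonomy <- function() {
  n_cl <- sample(2:3, 1); n_fam <- sample(n_cl:5, 1)
  n_gen <- sample(n_fam:8, 1); n_sp <- sample(n_gen:16, 1)
  fam_of <- sample(rep(seq_len(n_fam), length.out = n_gen))
  gen_of <- sample(rep(seq_len(n_gen), length.out = n_sp))
  has_tribe <- sample(c(TRUE, FALSE), n_fam, TRUE)
  taxonomy_table(data.frame(
    species_name = paste0("Genus", gen_of, " sp", seq_len(n_sp)),
    genus = paste0("Genus", gen_of),
    tribe = ifelse(has_tribe[fam_of[gen_of]],
                   paste0("Tribe", fam_of[gen_of]), NA_character_),
    family = paste0("Fam", fam_of[gen_of]),
    clade = paste0("Clade", rep(seq_len(n_cl), length.out = n_fam)[fam_of[gen_of]]),
    stringsAsFactors = FALSE))
}

random_hitset <- function(taxonomy, max_hits = 6L) {
  n <- sample(1:max_hits, 1)
  species <- taxonomy$species_name
  genera <- unique(taxonomy$genus)
  rank <- sample(c("species", "genus"), n, TRUE, prob = c(0.8, 0.2))
  label <- ifelse(rank == "species", sample(species, n, TRUE),
                  sample(genera, n, TRUE))
  # coarse bitscore levels force frequent ties at the maximum
  bits <- sample(c(100, 100, 100, 95, 90), n, TRUE)
  hitdf(label, rank, bits)
}

# R-side sliding-window oracle for the trim point
trim_point_R <- function(q_int, window, thresh) {
  n <- length(q_int)
  if (n < window) return(n)
  for (s in seq_len(n - window + 1L)) {
    if (mean(q_int[s:(s + window - 1L)]) < thresh) return(s - 1L)
  }
  n
}

small_config <- function(seed = 42L, ...) {
  generator_config(seed = seed, reads_per_sample = 500L,
                   months = data.frame(year = c(2016L, 2016L, 2017L, 2017L),
                                       month = c(5L, 9L, 4L, 5L)), ...)
}
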