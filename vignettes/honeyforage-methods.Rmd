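---
title: "Methods: from honey amplicon reads to forage composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from honey amplicon reads to forage composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(honeyforage)
```

## The problem

DNA metabarcoding of honey reads out which plants honeybees foraged on: the
chloroplast *rbcL* marker is amplified from pollen DNA in the honey,
sequenced as paired-end Illumina reads, and matched against a curated plant
reference database. `honeyforage` implements the whole desk-side analysis
for a multi-hive, multi-season study design — reference curation, read
processing, taxonomic assignment, forage-abundance banding, comparison with
floral surveys, and a multivariate count model of temporal change — plus a
synthetic-data generator so every stage can be validated against a known
truth without any sequence download.

## Reference database with genus fallback

The database is driven by a regional species list. Pool records labelled
with a listed species are kept verbatim; for every listed species with no
species-rank record, records labelled with its *genus* (at genus rank) are
pulled in as a fallback, tagged `genus_fallback`. Name matching is exact on
normalized binomials (whitespace collapsed, genus capitalized, infraspecific
labels truncated) — no fuzzy matching, so every inclusion is auditable.
Fallback deliberately adds genus-labelled records only, not species records
of congeners: that is the narrowest reading of "extracting records at the
genus level", and congener records would silently license wrong
species-level calls. Coverage is reported two ways: the share of listed
species with a species-rank record, and the share whose genus carries any
record (a congener's species record counts). The generator's default
scenario reproduces the coverage regime of real rbcL databases
(57% species-level).

## Read processing

* **Quality trimming** is a sliding-window scan (default 4 bp window, mean
  Phred < 20 cuts, minimum mate length 100): full windows are scanned from
  the 5' end and the read is truncated at the start of the first failing
  window. These defaults are stated in the configuration because the
  upstream tools they reproduce are commonly run with exactly these values.
* **Merging** overlaps read 1 with the reverse complement of read 2,
  ungapped. The accepted overlap maximizes *matches minus mismatches* (ties
  to the longer overlap). A pure matches-maximizing criterion is unusable in
  practice: after tail-trimming, a long spurious overlap with ~25% chance
  matches can outscore a shorter true overlap; penalizing mismatches makes
  the true overlap dominate for any realistic error rate. Acceptance
  additionally requires at least 10 bp of overlap with a mismatch fraction
  at most 0.25, and within the overlap the higher-quality base wins (read 1
  on ties). Merged reads shorter than 450 bp are discarded — the *rbcL*
  amplicon-length filter; primers are not removed.
* **Dereplication/clustering** at 100% identity is exact string equality of
  full-length merged reads, pooled across all samples; a sequence seen only
  once *across all samples* is a singleton and removed. Clusters are ordered
  by (total count desc, sequence asc), so the table is invariant to read
  order.
* **Sample exclusion** drops samples with strictly fewer than 100 retained
  reads, after singleton removal.

## Taxonomic assignment

Each cluster representative is scored against the reference database by
gapped local alignment (match +1, mismatch −2, gap opening 0, gap extension
2.5 per base) and raw scores are expressed in bits,
$(\lambda S - \ln K)/\ln 2$ with megablast-like constants
($\lambda = 1.28$, $K = 0.46$); all parameters are configurable. Two
performance devices stand in for a full alignment search, both standard in
this field's tools: an exact 14-mer seed screen restricts scoring to
references sharing at least one seed with the query (queries sharing no
14-mer with any reference — in effect random noise — get empty hit lists),
and the dynamic program is banded (half-width 30) around the main diagonal.
The band comfortably covers the substitution-dominated divergence of
congeneric *rbcL* sequences; alignments needing more than 30 net indels
would be scored pessimistically.

The top 20 hits by bitscore are kept (ties at the cut retained) and the
consensus rule operates on the *maximal-bitscore subset*, with ties detected
at a relative tolerance of 1e−9 to absorb floating-point jitter; sub-maximal
hits are recorded but do not vote:

1. a single species → species-level call;
2. several species of one genus (or any genus-labelled record) → genus;
3. several genera within one tribe → tribe; within one family → family;
4. families from *different clades* → `chimeric_excluded`;
5. several families within a *single* clade → `unassigned`. No rule is
   defined for this middle case; exclusion with an explicit tally is the
   conservative choice and is logged rather than silently mapped to a rank.

Genus-labelled records can never produce a species call. Assigned clusters
are summed into a samples × taxa read table; chimeric and unassigned reads
go to a discard tally, and the rank-level breakdown of assigned reads is
reported. A verification report flags (never removes) taxa absent from the
floral survey or detected outside their flowering window, mirroring the
manual botanical-veracity check of metabarcoding practice.

## Forage categories and traits

Monthly relative read abundance (RRA) pools read counts over a month's
samples and divides by the month's total — "sequences found in each month"
reads as pooled counts; a mean-of-per-sample-proportions variant is provided
as an option. Banding: major > 10%, secondary (1%, 10%], minor
(0.01%, 1%], occasional (0, 0.01%]. Only the "over 10%" bound is stated
strictly by the convention this reproduces, so the remaining boundaries are
taken closed above: exactly 10% is secondary, exactly 0.01% occasional.
Years are banded independently. Trait summaries (native status, growth
form, main habitat) cover species-, genus- and tribe-rank taxa;
family-rank taxa carry no traits, are excluded before computing, and the
proportions are renormalized over categorized reads with the excluded mass
logged — a missing trait record for any categorizable taxon is a hard
error, not a silent gap.

## Survey comparison

Genera in flower in a month are the union over survey zones (so merging
zones changes nothing). Honey taxa map to genera — species to their genus,
genus to itself; tribe- and family-rank taxa are expanded to the
survey-recorded genera of that tribe/family, or kept once as an unresolved
pseudo-genus when the survey records none. This expansion is an explicit
interpretation (logged per taxon): genus tallies that include tribe-level
detections are only reproducible under some such rule. Percentages are
rounded half away from zero to integers, matching how such tables are
printed (12.5% → 13%); base R's round-half-to-even would disagree on
several cells. Carryover analysis attributes a month's reads to taxa whose
genera were not in flower that month but had flowered in *any* earlier
surveyed month (including the previous autumn); taxa never surveyed at all
are excluded from the carryover fraction and reported separately.

## Composition statistics

Temporal change is tested with a multivariate negative-binomial GLM in the
manner of `mvabund::manyglm`: one NB regression (log link) per taxon,
sharing the design matrix (month, year factors) and a per-sample offset of
log total reads; the multivariate statistic sums per-taxon likelihood
ratios. Dispersion is estimated per taxon by profile maximum likelihood
(Newton updates alternating with IRLS); when the Newton step hits
non-positive observed information, a bracketed bisection on the profile
score takes over, and a method-of-moments estimate is the flagged last
resort. The dispersion is capped at $\theta \le 10^5$ (dispersion
$1/\theta \ge 10^{-5}$): beyond that the NB profile is numerically flat and
indistinguishable from Poisson while large-argument `lgamma` differences
start losing precision. All-zero taxa are skipped with a warning.

Inference is by **parametric bootstrap from the reduced model**: counts are
redrawn from each taxon's fitted reduced NB, both models refitted, and the
multivariate LR recomputed. `mvabund`'s default is PIT-trap residual
resampling; the parametric bootstrap was chosen instead because it is
simpler and exactly well-defined for NB counts — this is a documented
deviation, not claimed equivalent. The p-value uses the add-one estimator
$(1 + \#\{LR^* \ge LR\})/(1 + B)$, so 999 resamples floor at 0.001.
Samples from a month present in only one year can be excluded via
`exclude_samples` to keep the years comparable. Bray–Curtis dissimilarities
are computed on per-sample read proportions (the input an NMDS would use;
ordination itself is out of scope).

## The synthetic scenario

`simulate_dataset()` emulates the target study design: 2 apiaries × 3
hives sampled monthly April–September over two years with the first April
missing (11 months, 66 samples), 20,000 read pairs per sample, a 40-species
taxonomy over 15 genera, 6 families and 3 clades, ~500 bp amplicons read as
2 × 300 bp. Planted structure, all recorded in a truth ledger:

* tiered monthly compositions (two major, three secondary, two minor, one
  occasional taxon per month, Dirichlet-jittered per sample with
  concentration 300) so every forage band is exercised;
* species-level reference coverage 0.57 with genus fallback, two "orphan"
  species whose genus has no record at all, a sequence-identical twin pair
  (forcing genus-rank calls), and one short-amplicon taxon whose merged
  reads fail the 450 bp filter;
* substitution errors at 0.002/base, chimeras at rate 0.02 spliced at five
  fixed relative breakpoints (so identical chimeras recur and survive
  singleton removal — a uniformly random breakpoint would make every
  chimera a singleton and the chimera rule untestable end-to-end), and 1%
  unique random noise reads that can never survive singleton removal;
* a "carryover" autumn-flowering herb planted at ~5% of April-year-2 reads,
  and a never-surveyed "invader" in late summer;
* a quality model of flat Phred 37 with a Phred-10 50 bp tail on 5% of
  second mates. Mutations are applied to the amplicon before splitting into
  mates, so mates are consistent and a correct merge reconstructs the
  (mutated) amplicon exactly.

Major and secondary slots are drawn from genus-covered species — in real
databases the common forage plants are precisely the well-referenced ones —
which keeps recovery identifiable at genus level under partial coverage.
Truth for recovery checks is the ledger's *realized* retained read counts
(not the drawn proportions), so the noiseless pipeline is expected to be
exact, not merely close. Sequences are i.i.d. uniform bases with fixed
per-rank divergence (2%/base species-to-genus-base) rather than a realistic
*rbcL* substitution model: classification depends on score ordering, not
biochemistry. The generator does not model PCR/copy-number bias (RRA is
semi-quantitative), indels, position-dependent error profiles, or
quality-score realism beyond the planted tails — so passing tests show the
*pipeline logic* is correct under its stated error model, not that real
honey data would be recovered at the same accuracy.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run the noiseless end-to-end
check at 4,000 reads per sample (its exactness does not depend on depth)
and the noisy recovery check at the full 20,000 reads per sample across all
11 months; consensus-vs-oracle equivalence uses 10,000 randomized hit sets;
LR-test calibration uses 24 samples × 20 taxa × 199 resamples × 500 null
replicates. Unit tests use smaller fixtures built in code.

## Known limitations

* 100% clustering tolerates no terminal-gap differences; prefix-tolerant
  clustering would merge staggered duplicates differently.
* The banded aligner underestimates alignments requiring > 30 net indels.
* Tribe/family-to-genus expansion in the survey comparison is an
  interpretation; alternatives (counting such taxa once, or dropping them)
  change the genus tallies.
* The bootstrap LR test is calibrated for the NB family it simulates from;
  gross NB misspecification is not covered by the calibration check.
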