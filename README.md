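# honeyforage

Plant composition of honey from *rbcL* DNA metabarcoding.

`honeyforage` is for researchers studying honeybee foraging: it turns
paired-end *rbcL* amplicon reads from honey samples — plus a regional
species list, a reference sequence pool, a taxonomy and a floral survey —
into a per-sample plant read table, monthly forage categories,
trait/habitat summaries, a honey-versus-survey availability comparison, and
a statistical test of how honey composition changes through the season.

The pipeline implements, end to end:

* **Reference curation.** Pool records for listed species are kept; listed
  species with no species-rank record fall back to genus-labelled records
  (`genus_fallback`). Coverage is reported at species and genus level.
* **Read processing.** Sliding-window quality trimming; ungapped overlap
  merging (overlap maximizing matches − mismatches, ≥ 10 bp, ≤ 25%
  mismatches; merged reads < 450 bp discarded); exact dereplication and
  100%-identity clustering across all samples; removal of singletons
  (sequences seen once across *all* samples); exclusion of samples with
  < 100 retained reads.
* **Taxonomic assignment.** Seeded, banded, gapped local alignment against
  the reference database; bitscores `(λS − ln K)/ln 2` with
  megablast-like scoring (match +1, mismatch −2, gap 2.5/base). The top 20
  hits are summarized and the maximal-bitscore set decides: one species →
  species; one genus → genus; one tribe/family → that rank; families from
  different clades → chimeric, excluded; several families within one clade
  → unassigned.
* **Forage categories.** Monthly relative read abundance (RRA, pooled per
  month), banded: major > 10%, secondary 1–10%, minor 0.01–1%, occasional
  < 0.01%; plus per-trait (status/form/habitat) read proportions and
  cross-year consistency labels.
* **Survey comparison.** Genera detected in honey versus genera in flower
  per month (overlap % and proportion of available genera used, rounded
  half-up), and the fraction of reads carried over from taxa that flowered
  only in earlier months.
* **Composition statistics.** A manyglm-style multivariate
  negative-binomial GLM — one NB fit per taxon with a log-total-reads
  offset — tested by parametric-bootstrap likelihood ratio
  (`p = (1 + #{LR* ≥ LR})/(1 + B)`), and Bray–Curtis dissimilarities on
  read proportions.
* **Synthetic data.** `simulate_dataset()` generates every input with a
  ground-truth ledger (seasonal compositions, coverage gaps, twins,
  chimeras, singleton noise, a carryover taxon and an unsurveyed invader),
  so the whole pipeline is testable offline.

## Worked example

Simulate a two-month study at reduced depth, run the pipeline, and test for
a month effect:

```r
library(honeyforage)

cfg <- generator_config(seed = 7, reads_per_sample = 2000,
                        months = data.frame(year = c(2016, 2016),
                                            month = c(5, 6)))
ds <- simulate_dataset(cfg)
pl <- run_pipeline(ds)
print(pl$coverage)
#> reference coverage: species 57%, genus 95% (n = 40 listed species)
print(pl$taxon_table)
#> taxon_read_table: 12 samples x 11 taxa, 14398 assigned reads
#>   rank breakdown: species 30%, genus 70%, tribe 0%, family 0%
#>   discarded reads: chimeric 8, unassigned 0

full <- fit_nb_glm(pl$taxon_table, ds$metadata, ~ month)
red  <- fit_nb_glm(pl$taxon_table, ds$metadata, ~ 1)
print(lr_test(full, red, n_resamples = 199, seed = 1))
#> multivariate LR = 436.64, P = 0.005 (199 resamples)
```

The coverage line mirrors the generator's configured reference gaps (57% of
species have species-rank records; two orphan species leave genus coverage
below 100%). The rank breakdown shows the expected consequence of partial
coverage: reads from uncovered species are recovered at genus rank through
the fallback records. The LR test rejects no-month-effect at the resampling
floor's scale because the two months were planted with different
compositions; monthly abundances themselves come from
`monthly_rra(pl$taxon_table, ds$metadata)`, banded into forage categories.

A command-line front end over the same functions is installed at
`inst/scripts/honeyforage.R` (subcommands `synth`, `refdb`, `reads`,
`classify`, `traits`, `survey`, `stats`).

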