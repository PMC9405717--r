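Package: honeyforage
Title: Plant Composition of Honey from rbcL DNA Metabarcoding
Version: 0.1.0
Authors@R: person("Honeyforage", "Developers", email = "honeyforage@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of honeybee forage use from pollen DNA
    metabarcoding of honey. Builds a curated rbcL reference database from a
    regional species list with genus-level fallback, processes paired-end
    amplicon reads (quality trimming, overlap merging, exact dereplication
    and 100 percent-identity clustering with singleton removal), assigns
    clusters to plant taxa by a top-bitscore consensus over local-alignment
    hits with cross-clade chimera exclusion, bands monthly relative read
    abundance into forage categories, compares genera detected in honey with
    floral-survey availability, and tests temporal change in honey
    composition with a multivariate negative-binomial GLM using a
    log-total-reads offset and resampled likelihood-ratio inference. A
    synthetic-data generator with a ground-truth ledger makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    MASS,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
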