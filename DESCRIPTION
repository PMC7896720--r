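Package: radqc
Title: RADseq Genotype Filtering Diagnostics and Hierarchical Length-at-Age
    Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing and removing bioinformatic artifacts from
    RADseq SNP genotype panels before population-structure inference, and for
    fitting a hierarchical Bayesian length-at-age model with region-by-period
    contrasts. Reads and writes genepop files; computes missingness profiles,
    Weir-Cockerham F-statistics, exact tests of genic differentiation, and
    HDplot paralog diagnostics; applies an ordered, audited filter cascade
    (individual missingness, per-population genotyping rate including the
    flawed k-of-n variant, pooled-pair F_IS thresholds, HDplot bands); runs
    mean-imputed individual PCA to expose missingness-driven false structure;
    and characterizes per-locus F_ST distributions with subsample
    normalization. A synthetic-data module generates genotype panels with
    controllable divergence (Balding-Nichols), population-specific missingness,
    undersplit (merged-paralog) and oversplit loci with read depths, plus
    growth datasets from the hierarchical model, so every stage is testable
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
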