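Package: ervfootprint
Title: Epigenetic Sequence Footprints of Retroviral Endogenization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for detecting the epigenetic sequence footprints
    that endogenization leaves in retroviral genomes. Computes observed/expected
    k-mer ratios (D-ratios) under a first-order Markov background, tests for the
    methylated-cytosine deamination signature (CpG loss mirrored by TpG/CpA
    gain), calls CpG islands with sliding-window Gardiner-Garden criteria,
    summarizes Bismark-style per-cytosine methylation reports by trinucleotide
    context, detects APOBEC3G-driven G-to-A hypermutation with a
    context-stratified Fisher test, and scores motif-set enrichment between
    endogenous and exogenous sequence sets with a strict presence-based
    significance rule. Ships a mechanistic simulator of methylation-driven CpG
    decay so every estimator is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
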