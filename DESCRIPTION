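Package: pleiofit
Title: Barcode Lineage Tracking, Pooled Fitness Inference, and Pleiotropy
    Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for pooled fitness competition experiments with
    double-barcoded yeast lineages. Covers the full path from raw
    paired-end amplicon reads to biological conclusions: UMI-aware
    barcode extraction with a fuzzy-flank regular expression,
    deletion-neighborhood error correction of barcodes (Levenshtein
    clustering), chimera and cross-lane artifact removal, GC-bias and
    home-environment quality filters, neutral-scaled per-generation
    selection-coefficient estimation from log-frequency slopes with
    inverse-variance replicate combination, curation of adaptive
    mutations from externally called variant tables, and classification
    of pleiotropic fitness profiles across environments. A serial-
    transfer simulation engine generates ground-truth lineages, count
    trajectories, and raw reads with realistic error processes so every
    stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
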