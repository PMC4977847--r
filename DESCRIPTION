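Package: crossmir
Title: Cross-Kingdom miRNA Target Prediction, Network Weighting and
    Module-Level Functional Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for studying putative cross-kingdom
    microRNA regulation. Predicts miRNA-transcript hybridization sites with an
    internal intermolecular minimum-free-energy dynamic program under seed and
    structural constraints, calibrates empirical extreme-value p-values on
    dinucleotide-preserving shuffles, screens and ranks candidate targets,
    runs a three-level validation harness against known target lists, weights
    gene interaction networks by iterated-matrix PageRank, extracts bridge
    genes and decomposes the network into modules, and performs per-module
    hypergeometric GO enrichment with Benjamini-Hochberg adjustment, GO-slim
    grouping, cross-species functional-similarity scoring and three-tier
    tissue-expression classification. Ships synthetic-data generators with
    planted, recoverable structure so the whole pipeline is testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    igraph,
    ggplot2,
    generics,
    withr,
    yaml,
    jsonlite,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
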