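Package: casersa
Title: Single-Case Representational Similarity Analysis for Time-Resolved EEG Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-case (patient versus control group) representational
    similarity analysis of epoched EEG. Builds time-resolved representational
    dissimilarity matrices from pairwise cross-validated Fisher linear discriminant
    decoding (AUC dissimilarities), computes temporal generalization matrices by
    cross-correlating RDMs over time, compares brain RDMs with model RDMs (feature
    spaces, semantic embeddings, categorical codes) via partial Spearman
    correlation, and performs Crawford-Howell modified t-tests for case-control
    inference, including per-timepoint and time-by-time contrast maps. A synthetic
    EEG generator with a programmable time-varying representational geometry makes
    the whole pipeline testable end to end without access to patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
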