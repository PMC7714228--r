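Package: emgsynergy
Title: Muscle Synergy Dimensionality Analysis for Multichannel Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the dimensionality of forearm muscle activation from
    multichannel surface EMG under the muscle synergy framework. Implements
    envelope preprocessing (rectification, zero-lag Butterworth lowpass,
    decimation, rest removal, unit-variance normalization), non-negative matrix
    factorization by Frobenius multiplicative updates, cross-validated synergy
    number selection with dual variance-accounted-for criteria, typing of
    synergies by k-means clustering of movement-activation profiles under a
    correlation distance with silhouette model selection, classification of
    patient synergies against control synergy types, nonparametric group
    statistics, and a synthetic-data generator with known ground truth that
    emulates NinaPro-style recording sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    Rcpp,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    cluster,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
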