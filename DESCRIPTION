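Package: balancenet
Title: Time-Variant Directed EEG Connectivity Networks During Balance Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for estimating time-variant directed cortical connectivity
    from multi-trial EEG recorded during postural perturbation experiments.
    Implements multi-trial time-variant multivariate autoregressive (tvMVAR)
    modelling by linear Kalman filtering, time-variant generalized partial
    directed coherence (gPDC), matched multi-window Gabor time-frequency and
    phase-locking analysis with Rayleigh-test thresholding and harmonic
    artifact screening, directed-network construction with node-strength
    statistics (bootstrap confidence tubes, Bonferroni-corrected paired
    t-tests), and 4-mode nonnegative PARAFAC decomposition of the connectivity
    tensor. Ships a synthetic-data generator that emulates a stable-to-unstable
    balance experiment with known ground-truth couplings so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
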