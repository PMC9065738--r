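Package: untbx
Title: Neutral Community Assembly Tests for OTU Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing the neutral theory of biodiversity on
    community (OTU) count tables. Implements the Etienne sampling-formula
    likelihood for Hubbell's standard neutral model with maximum-likelihood
    fitting and an exact pseudo-P neutrality test, a hierarchical
    Dirichlet-process multi-site neutral model fitted by Gibbs sampling with
    metacommunity- and local-level neutrality tests, the Sloan near-neutral
    model with per-species neutral/above/below classification, the
    (normalized) stochasticity ratio built on Ruzicka similarity and
    pluggable null models, and a simulation-based power analysis of the
    neutrality test against intrinsic-fitness and density-dependent
    non-neutral community generators. Ships urn-scheme simulators for
    neutral and non-neutral community assembly so every analysis can be
    exercised on synthetic data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
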