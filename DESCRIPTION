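Package: qrer
Title: Quasi-Rerandomization Weights for Observational Causal Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Covariate balancing weights for observational studies that
    explicitly target a rerandomized experiment. A rerandomization engine
    draws treatment allocations with fixed group sizes and accepts them by
    Mahalanobis distance; a generative transformation of Dirichlet weight
    vectors is then trained, by minimizing a kernel maximum mean discrepancy
    between weighted and rerandomized covariate mean differences plus two
    balance and dispersion regularizers, so that the weighted data mimic the
    balance distribution of the rerandomized experiment. Includes weighted
    difference-in-means and ensembled treatment-effect estimators with
    heteroskedasticity-robust inference, and a simulation benchmark with
    three covariate scenarios and three response surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "installed")
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
    sandwich,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
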