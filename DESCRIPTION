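Package: cenmediate
Title: Mediation Analysis with a Categorical Exposure and a Right-Censored Mediator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage semiparametric estimation and inference for causal
    mediation models in which a categorical exposure (for example an
    additive-coded SNP genotype) acts on a continuous or binary outcome
    through a right-censored mediator. Stage one fits an accelerated
    failure time model to the mediator by inverse-probability-of-censoring
    weighted least squares and estimates the residual distribution by the
    Kaplan-Meier estimator; stage two maximizes a pseudo-likelihood that
    integrates censored mediators over that residual distribution. The
    package provides per-category and frequency-weighted overall natural
    indirect, direct, and total effects, the proportion mediated,
    bias-corrected and accelerated (BCa) bootstrap confidence intervals,
    inverse-prevalence sampling weights for case-control designs, and a
    simulation engine with Hardy-Weinberg genotype generation and
    censoring-rate calibration.
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
    optparse,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
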