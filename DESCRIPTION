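Package: tvdbn
Title: Time-Varying Gene-Regulation Networks from Time-Course Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-gene inference of time-varying gene-regulation networks from
    time-course expression data. Models each target gene as a piecewise
    lag-1 autoregression on a set of candidate regulators, with changepoints
    delimiting regulatory phases. A reversible-jump Markov chain Monte Carlo
    sampler explores the joint space of changepoint configurations and
    phase-specific parent sets, with regression coefficients and noise
    variances marginalised analytically under conjugate priors. Networks are
    selected from the posterior sample by a Bayes-factor procedure. Includes
    a synthetic-data generator (wild-type and knock-out designs) and
    positive-predictive-value / sensitivity benchmarking of changepoint and
    edge recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    pracma,
    withr
Config/testthat/edition: 3
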