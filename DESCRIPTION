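Package: itcbayes
Title: Bayesian Analysis of Isothermal Titration Calorimetry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring binding thermodynamics (free energy,
    enthalpy, dilution heats, concentrations and instrument noise) from
    integrated isothermal titration calorimetry (ITC) injection heats.
    Implements a Bayesian model with lognormal concentration priors and a
    Jeffreys noise prior, sampled by Metropolis-within-Gibbs MCMC, together
    with the standard nonlinear least-squares analysis, shortest
    (highest-density) credible intervals, interval-coverage calibration
    curves, kernel-density Kullback-Leibler comparison of posteriors, and a
    simulator for synthetic titration experiments with concentration and
    heat noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    minpack.lm,
    generics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    readr
Config/testthat/edition: 3
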