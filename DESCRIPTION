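Package: nichecast
Title: Presence-Only Niche Models and Climate-Scenario Range Forecasting
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Maximum-entropy presence-background species distribution
    modelling with an ensemble climate-scenario forecasting pipeline:
    L1-regularized maxent fitting over target-group background points,
    null-model AUC significance testing, dual-threshold range binarization
    (fixed cumulative 10 and minimum training presence), dispersal-buffer
    clipping against documented ranges, percent habitat change across
    circulation-model x emissions x threshold scenarios, stacked species
    richness mapping with paired-t comparisons, and a factorial general
    linear model of percent habitat loss. Includes a synthetic-landscape
    generator (correlated autocorrelated bioclimatic covariates, virtual
    species with known truth, biased occurrence sampling) so the whole
    pipeline is testable against a known species-environment relationship.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    car,
    geosphere,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
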