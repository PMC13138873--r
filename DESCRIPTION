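Package: isatdm
Title: Population Pharmacokinetics and Virtual Therapeutic Drug
    Monitoring of Isavuconazole
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for population pharmacokinetic analysis of the
    triazole antifungal isavuconazole and for simulation-based appraisal
    of therapeutic drug monitoring (TDM) strategies. Implements a
    one-compartment model with first-order absorption, log-normal
    interindividual variability on clearance and volume, and a mixed
    (proportional plus additive) residual error model; nonlinear
    mixed-effects estimation by Laplace approximation with
    likelihood-ratio and AIC model comparison, stepwise covariate
    selection, conditional weighted residuals, nonparametric bootstrap
    and prediction-corrected visual predictive checks; MAP-Bayes
    individual exposure estimation; exploratory exposure-response and
    exposure-toxicity logistic regressions; a synthetic TDM-cohort
    generator; and a 10,000-virtual-patient steady-state simulator
    comparing proportional and model-informed precision dosing (MIPD)
    dose-adjustment rules against trough-concentration and AUC targets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
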