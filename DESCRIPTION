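Package: civipk
Title: Population Pharmacokinetics of Continuous Intravenous Infusion Regimens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear mixed-effects analysis of sparse concentration data from
    continuous intravenous infusion (CIVI) regimens, built around the 7-day
    infusion schedule used for the survivin suppressant sepantronium. Provides a
    closed-form one-compartment infusion model, an FOCE-with-interaction
    (Laplace at the conditional mode) marginal-likelihood engine with a single
    exponential random effect on clearance and two proportional residual-error
    groups, IQR-based outlier flagging, Cockcroft-Gault renal function,
    stepwise covariate selection by likelihood-ratio test, nonparametric
    bootstrap validation with percentile confidence intervals, steady-state
    exposure (Css) prediction, and a virtual-study simulator for the full
    trial design so every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
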