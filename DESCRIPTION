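Package: cefoneo
Title: Developmental Population Pharmacokinetics and Dose Evaluation of
    Cefotaxime in Neonates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Nonlinear mixed-effects analysis of sparse cefotaxime
    concentration data from neonates with early-onset sepsis. Implements a
    one-compartment intravenous-infusion structural model with allometric
    current-weight scaling and postnatal-age maturation of clearance,
    first-order conditional estimation with interaction (FOCE-I), stepwise
    covariate selection by likelihood-ratio testing, model evaluation by
    non-parametric bootstrap, normalized prediction distribution errors and
    prediction-corrected visual predictive checks, and steady-state dose
    evaluation against a free-drug time-above-MIC target. A synthetic-cohort
    generator reproduces the opportunistic two-samples-per-neonate study
    design so the whole pipeline runs without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    jsonlite,
    ggplot2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
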