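Package: vancopk
Title: Population Pharmacokinetics and Dose Optimization of Vancomycin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population pharmacokinetic modelling of intravenous vancomycin in
    adults across the full range of renal function, including augmented renal
    clearance. Implements closed-form one- and two-compartment infusion
    kinetics, a saturable creatinine-clearance covariate model for drug
    clearance and an intensive-care covariate on central volume, first-order
    conditional estimation with interaction (FOCE-I) for nonlinear
    mixed-effects fitting, stepwise covariate selection, goodness-of-fit and
    prediction-corrected visual predictive check diagnostics, nonparametric
    bootstrap, and Monte Carlo probability-of-target-attainment simulation
    yielding renal-function-stratified dosing recommendations. A synthetic
    cohort generator reproduces the demographic, dosing and sampling design
    of a retrospective hospital therapeutic-drug-monitoring population so the
    whole workflow is testable without confidential patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    ggplot2
Config/testthat/edition: 3
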