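Package: teicopk
Title: Population Pharmacokinetics and Dosing Optimization of Teicoplanin
    in Renal Transplant Recipients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-compartment intravenous-infusion pharmacokinetics with
    closed-form superposition over multi-dose regimens, a hierarchical
    population layer (creatinine-clearance dependent clearance, exponential
    inter-individual variability, log-scale residual error), a first-order
    conditional (Laplace-at-mode) nonlinear mixed-effects estimation engine
    with stepwise covariate modeling and nonparametric bootstrap, model
    diagnostics (goodness-of-fit residuals, prediction-corrected visual
    predictive checks, external-validation error metrics), and a Monte Carlo
    dosing-optimization engine that computes probability of target attainment
    for trough and AUC/MIC targets across renal-function strata. Includes a
    synthetic-cohort generator emulating a sparse therapeutic drug monitoring
    design in renal transplant patients, so the whole workflow is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, graphics, grDevices, utils
Suggests: testthat (>= 3.0.0), deSolve, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
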