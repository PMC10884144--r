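Package: adamhmm
Title: Bivariate Mixed Hidden Markov Modelling of Anti-Drug Antibody
    Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to infer a subject's hidden anti-drug-antibody (ADA)
    production state from two longitudinal observed variables:
    individually weighted population pharmacokinetic (PK) residuals and
    ADA assay measurements. Implements a one-compartment population PK
    stage fitted to first-dosing-occasion data with empirical-Bayes
    individual parameters, a two-state hidden Markov model with bivariate
    Gaussian emissions and logit-linked transition probabilities,
    maximum-likelihood estimation of six model variants with optional
    inter-individual variability integrated by Gauss-Hermite quadrature,
    Viterbi state decoding, model-based simulation, a clinical-trial
    cohort simulator, and diagnostics comparing decoded state sequences
    with threshold-based clinical ADA classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
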