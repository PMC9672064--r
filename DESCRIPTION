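Package: voxelsurv
Title: Voxel-Based Survival Risk Models for Multi-Site Structural MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds individual risk-prediction models from voxel-based
    morphometry maps combined with clinical variables, for right-censored
    time-to-event outcomes (and gaussian or binomial labels).  Implements
    leakage-free multi-site harmonization with empirical-Bayes batch
    correction estimated on training subjects only, train-frozen
    residualization of age and sex effects, L1-penalized regression by
    cyclic coordinate descent with internally cross-validated penalty
    selection, subject-bootstrap and half-brain voxel ensembles,
    event-stratified k-fold cross-validation, and site-aware accuracy
    evaluation with a random-intercept Cox model.  Includes a multi-site
    synthetic cohort generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    survival,
    RNifti,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    sva,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
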