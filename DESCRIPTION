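Package: cakival
Title: External Validation Toolkit for Cisplatin-Associated AKI Risk Scores
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements the external-validation workflow for two points-based
    clinical prediction models of cisplatin-associated acute kidney injury
    (C-AKI): the Motwani and Gupta simple scores. Provides KDIGO-anchored
    outcome labelling from serum-creatinine trajectories, regression-based
    single imputation of missing baseline laboratory values, score-to-
    probability mapping (fixed odds-ratio mapping and a pluggable restricted
    cubic spline mapper), discrimination/calibration/overall-fit estimation
    with bootstrap inference (AUROC, calibration-in-the-large, calibration
    slope, Brier score), logistic recalibration, Gupta-score risk
    stratification, and decision curve analysis. A seeded synthetic-cohort
    generator emulating a Japanese oncology cohort's covariate marginals,
    lab missingness, outcome prevalences and score discrimination makes the
    entire pipeline testable without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite, graphics
Suggests: testthat (>= 3.0.0), withr, pROC, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
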