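Package: tremorkit
Title: Tremor Detection Pipelines for 3D Motion-Capture Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the presence or absence of tremor in 3D optical
    motion-capture marker trajectories, per body extremity. Implements six
    detection pipelines used in clinical movement analysis: two rule-based
    spectral-peak detectors (velocity-domain winner-take-all and
    displacement-amplitude max aggregation), their hybrids with support
    vector machine classifiers on the same engineered spectral features,
    and two generic-spectral classifiers (SVM and gradient boosting) on a
    61-point smoothed Welch power spectral density feature vector. Includes
    TRC/CSV kinematic file input and output, a seeded synthetic
    motion-capture simulator for end-to-end testing without clinical data,
    stratified k-fold cross-validation, and confusion/ROC/PRC reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    xgboost,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
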