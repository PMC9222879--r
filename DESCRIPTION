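Package: icuflow
Title: ICU Patient-Flow Simulation and Discharge-Readiness Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying discharge readiness of cardiovascular
    patients in intensive care units. Provides a synthetic generator for a
    MIMIC-III-shaped relational cohort (patients, admissions, ICU stays,
    prescriptions, chart events) with exactly reproducible marginals and a
    planted discharge-readiness signal; a discrete-time ward-flow model of
    bed occupancy, primary/secondary hospitalization rates, overflow
    queueing and inspection-driven discharges; preprocessing (invasive
    blood-pressure backfill, median and tree-based imputation, ordinal
    encoding) into a flat per-stay feature table; a regression model zoo
    (decision tree, gradient-boosted variants with early stopping,
    auto-tuned stochastic-gradient linear regression, and three stacked
    blenders) with grid search; and partition experiments reporting
    residual-mean and accuracy metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rpart,
    xgboost,
    nnet,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
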