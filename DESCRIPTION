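Package: score2pro
Title: Subgroup-Stratified Proteomic Risk Prediction for Incident Myocardial Infarction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for building and evaluating clinical
    subgroup-stratified plasma-proteomic risk prediction models for incident
    myocardial infarction. Provides a survival-cohort simulator with planted
    (optionally subgroup-conditional) protein hazards, inclusion filtering and
    leakage-safe preparation, per-protein Cox proportional-hazards screening
    with Bonferroni control, gradient-boosting importance ranking with
    sequential forward panel selection under a DeLong/AUC plateau stopping
    rule, and the evaluation statistics the framework rests on: AUC, DeLong
    tests, time-horizon dynamic AUC, categorical net reclassification
    improvement with bootstrap inference, bootstrap optimism correction and
    leave-one-region-out cross-validation. An orchestration layer runs the
    ten one-variable clinical subgroups, the 32-cell composite sweep and the
    high-risk reclassification analysis end to end from a single config.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    xgboost,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    rpart,
    optparse
Config/testthat/edition: 3
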