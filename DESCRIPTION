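Package: dgfsd
Title: Mortality-Risk Assessment for Sepsis via Autoencoder-Fused Graph
    Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements DGFSD, a deep mortality-risk classifier for ICU sepsis
    patients that fuses per-patient autoencoder representations into a graph
    convolutional network built over a top-k patient-similarity graph, together
    with the surrounding analysis pipeline: synthetic sepsis-like cohort
    generation, indicator-level missingness filtering, reference-value
    imputation, stratified train/test splitting, SMOTE class rebalancing,
    gradient-boosting importance ranking for core-indicator selection, and a
    baseline/ablation evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    xgboost,
    rpart,
    class,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
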