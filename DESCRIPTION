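Package: lipidcad
Title: Lipidomic Risk Scoring for Subclinical Coronary Artery Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for plasma-lipidomic association
    with subclinical coronary artery disease (sCAD): synthetic cohort
    generation with planted ground truth, calcium-percentile sCAD labelling,
    pseudo-replicate RUV-III batch-effect removal with frozen transfer to a
    validation cohort, per-species logistic association with
    Benjamini-Hochberg control, a ridge-penalised lipid risk score (LRS)
    compared against the Framingham Risk Score (FRS), per-sample
    classifiability from repeated cross-validation with modifying-variable
    discovery, and paired ROC evaluation with DeLong's test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    glmnet,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
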