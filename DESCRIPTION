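Package: tmaquant
Title: Semi-Automated DAB Signal Quantification and Biomarker Evaluation for Tissue Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for evaluating candidate
    immunohistochemistry biomarkers on tissue-microarray (TMA) cores
    stained with the DAB chromogen. Per-core expression is measured by a
    two-threshold pixel count (amount of tissue, amount of DAB signal)
    whose ratio AmtS/AmtT is compared between high-risk and low-risk
    patient groups with an exact Mann-Whitney U test, empirical ROC
    analysis (DeLong and Hanley-McNeil standard errors, Youden operating
    point, likelihood ratios, post-test probabilities) and logistic
    combination of marker pairs. Thresholds are trained on a labelled
    subset by an exhaustive grid search maximising the coefficient of
    determination of ratio on group. A synthetic H-DAB core image
    generator with a hierarchical logit-normal signal model makes every
    stage testable without access to patient images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    png,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
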