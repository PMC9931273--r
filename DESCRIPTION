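Package: vicscore
Title: Sparse Clinical Risk Scores from Shapley Variable Importance Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds sparse, integer-point clinical risk scores from tabular
    cohort data with a binary outcome. Samples an ensemble of nearly-optimal
    logistic regression models by rejection sampling inside a 5% loss band,
    quantifies each model's reliance on every variable with Shapley additive
    global importance (SAGE) values and Monte-Carlo standard errors, pools
    importance across models by random-effects meta-analysis with 95%
    prediction intervals, derives a significance-filtered ensemble variable
    ranking, and turns the ranked list into an integer scoring table via
    automatic categorization, coefficient scaling and rounding, with a
    parsimony curve to pick the sparsest adequate model and full ROC/AUC
    evaluation. Includes a synthetic electronic-health-record style cohort
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    pROC,
    car
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
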