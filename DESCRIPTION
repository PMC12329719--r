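Package: wetrisk
Title: Wetland Antibiotic Removal Prediction and Regional Risk Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Machine-learning pipeline for antibiotic risk assessment in
    wetland systems. Fits and selects antibiotic removal efficiency (ARE)
    predictors (gradient boosting, random forest, k-nearest neighbours,
    support vector regression, and a KNN-boost hybrid) with 5-fold
    cross-validated hyperparameter search and a bootstrap ensemble for
    prediction intervals; imputes missing experiment features by iterative
    random-forest (missForest-style) imputation; propagates county-level
    antibiotic emissions through wetland inventories to mass-balance
    surpluses and minimum-PNEC ("cask effect") risk quotients; projects
    high-risk county area to 2035 under management, restoration and
    abatement policy scenarios; and interprets the fitted model with exact
    TreeSHAP attributions cross-checked by permutation importance. Includes
    a synthetic data generator emulating the statistical structure of
    wetland antibiotic-removal experiments and regional inventories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    xgboost,
    ranger,
    e1071,
    caret,
    kernlab
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
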