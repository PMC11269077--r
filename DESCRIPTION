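Package: chdrisk
Title: Risk Stratification and In-Hospital Mortality Prediction for
    Congenital Heart Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage analysis of in-hospital mortality after surgery for
    congenital heart disease. Stage one estimates per-procedure mortality with
    a Bayesian binomial random-effects (shrinkage) model, partitions
    procedures into ordered risk categories by exact dynamic programming on a
    case-weighted homogeneity criterion, and selects the number of categories
    by the Bayesian information criterion. Stage two trains a patient-level
    gradient-boosted mortality classifier with recursive feature elimination,
    grid search, Youden-index thresholding, and bootstrap confidence intervals
    for the area under the ROC curve. A synthetic-registry generator with a
    skewed procedure-volume law, logit-normal procedure heterogeneity, mixed
    covariates with missingness, and a logistic outcome model makes every
    stage testable without access to hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xgboost
Suggests:
    broom,
    knitr,
    lme4,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
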