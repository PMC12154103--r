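Package: xlcate
Title: X-Learner Estimation of Treatment Effects on Binary Health Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-stage X-Learner estimation of conditional average
    treatment effects (CATE) for binary outcomes in observational health
    surveys, with propensity-weighted combination, risk-difference effect
    inference based on the t distribution, a model-selection harness
    (accuracy, AUC, F1), permutation-sampling Shapley feature importance,
    survey screening and recoding utilities, and a synthetic cohort
    generator with known confounded treatment assignment and ground-truth
    effects for validation. Motivated by analyses of physical-activity and
    sedentary-behaviour interventions on depression, suicidal ideation and
    perceived stress in elderly national-survey cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    ranger,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
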