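Package: cprderive
Title: Derivation and Evaluation of Count-Based Clinical Prediction Rules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deriving clinical prediction rules (CPRs) of
    treatment success from baseline candidate predictors and longitudinal
    disability outcomes, as done for lumbar stabilization exercise
    programs in non-acute low back pain.  Classifies treatment response
    from Oswestry Disability Index change scores, dichotomizes continuous
    predictors by six cut-point criteria (ROC distance, median, Youden
    index, minimum |Se-Sp|, maximum positive likelihood ratio, and
    Kullback-Leibler distances), screens candidate tests with liberal
    chi-square and likelihood-ratio rules, selects predictors by
    three-step hierarchical backward-stepwise logistic regression, and
    converts the retained tests into a count-of-positive-tests rule with
    full diagnostic performance statistics (sensitivity, specificity,
    likelihood ratios, predictive values with confidence intervals) and
    Bayesian post-test probabilities of success.  Includes a calibrated
    synthetic-cohort simulator with planted predictor effects so the whole
    pipeline can be exercised and validated without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), pROC, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
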