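Package: cogstatus
Title: Dementia Classification from Low-Cost Survey Predictors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving cognitive status (normal cognition, cognitive
    impairment, dementia) from a neuropsychological battery with regression-based
    norms and informant IQCODE ratings, and for building parsimonious dementia
    classification models from low-cost predictors. Includes a synthetic cohort
    generator emulating a Brazilian ageing-survey data structure, deterministic
    scorers for the battery, IQCODE, CES-D8, IPAQ, handgrip strength, BMI,
    alcohol and social-contact instruments, k-nearest-neighbour imputation with
    elbow-based selection of k, balanced random-forest Gini importance ranking
    with stepwise out-of-bag error minimisation under repeated stratified
    cross-validation, multivariable logistic odds-ratio modelling, and
    imbalance-aware evaluation (G-mean, PR-AUC) with bootstrap confidence
    intervals.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
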