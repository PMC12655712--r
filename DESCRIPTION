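Package: milksupply
Title: Data-Driven Classification and Diagnosis of Low Milk Supply
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for defining and diagnosing low milk supply in
    breastfeeding dyads from 24 h test-weighing feed diaries. Computes
    milk production and infant intake from pre/post-feed weights,
    infant weight-for-age z-scores by the lambda-mu-sigma (LMS) method
    against a pluggable growth reference, and derived feeding and
    growth measures. Classifies mother-infant dyads by latent profile
    analysis (equal-variance diagonal Gaussian mixtures fitted by EM)
    with bootstrap likelihood ratio tests and multi-criterion model
    selection, derives diagnostic thresholds by ROC analysis with
    Youden-index cut-offs, and quantifies maternal risk factors via
    multinomial logistic regression with bootstrap stability selection
    and composite-factor models. Includes a calibrated synthetic-cohort
    generator with full ground-truth bookkeeping, descriptive-table and
    nonparametric group-comparison helpers, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils
Suggests:
    mclust,
    nnet,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
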