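Package: pvopredict
Title: Stability-Voting Transcript Selection and Classification for
    Preoperative Pulmonary Venous Obstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building peripheral-leukocyte transcript classifiers
    of preoperative pulmonary venous obstruction in total anomalous
    pulmonary venous connection (TAPVC). Implements a seeded negative-binomial
    synthetic-cohort generator, expression-matrix input/output with log
    transformation and train-set standardization, an imaging- and age-driven
    train/validation split, covariate-adjusted differential expression with
    Holm correction, an iterated elastic-net and random-forest feature-selection
    ladder aggregated by frequency voting, and elastic-net, random-forest and
    linear-SVM classifier heads evaluated by AUC, sensitivity, specificity,
    Cohen's kappa and F1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    ranger,
    kernlab,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
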