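Package: predinfer
Title: Corrected Inference for Regression on Machine-Learning-Predicted Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for post-prediction inference: recovering approximately
    unbiased coefficient estimates, standard errors and test statistics from
    downstream regression models whose dependent variable is a machine-learning
    prediction rather than an observed outcome. Provides an analytical
    correction for linear inference models and parametric/nonparametric
    bootstrap corrections for generalized linear inference models, built on a
    train/test/validation split in which a simple relationship model between
    observed and predicted outcomes is estimated on the testing set. Includes
    fully specified continuous and binary simulation scenarios and a
    replication harness that measures bias, rmse and type-I-error operating
    characteristics of corrected and uncorrected inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mgcv,
    caret,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
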