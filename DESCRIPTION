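Package: priorstack
Title: Transfer Learning for Penalized Regression with Calibrated Prior Effects
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-step transfer learning for high-dimensional generalized
    linear models (Gaussian and binomial) with multiple sources of numerical
    prior effects, such as regression coefficients or signed log10 p-values
    from external studies. Each source is first calibrated to the target data
    by exponential (power-law) or isotonic (sign- and order-preserving)
    calibration, sources are pre-filtered with a paired Wilcoxon residual
    test, co-data-free ridge or lasso baselines are fitted by cross-validated
    penalized regression, and everything is combined by stacked
    generalization with non-negative meta-weights, either on stacked
    cross-validated linear predictors (standard stacking) or jointly with
    penalized per-feature deviations (simultaneous stacking). The result is a
    single set of combined coefficients ready for prediction and
    interpretation. Includes simulation generators for external and internal
    benchmarking designs, percent-of-null evaluation metrics, model
    serialization to JSON, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
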