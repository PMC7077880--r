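Package: contextprob
Title: Context-Dependent Probability Estimation: Models, Simulation and
    Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the statistical context of a
    stimulus biases estimates of its reward probability. Implements the
    uncertainty- and reference-dependent (URD) family of probability
    estimation models together with divisive-normalization and
    range-normalization competitors, in both an equal-weight sliding-window
    framework and a Rescorla-Wagner delta-rule framework. Provides a
    simulator for two-stimulus context experiments with interval-button
    probability reports and post-task lottery choices, maximum-likelihood
    fitting with BIC model comparison and bootstrap confidence intervals,
    and the behavioral statistics used with such designs: context-effect
    deltas, trial-level frequency regressions, choice-probability tests and
    nonparametric subject-resampling bootstrap inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
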