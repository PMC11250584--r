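Package: stimmeta
Title: Hierarchical Bayesian Meta-Regression for Brain-Stimulation Study Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for relating transcranial direct current stimulation (tDCS)
    design parameters to behavioral effect sizes via hierarchical Bayesian
    meta-regression. Computes signed Hedges' g standardized mean differences
    for between- and within-subject designs, codes study-level moderators with
    sum-to-zero deviation contrasts and mean centering, fits a measurement-error
    random-effects model with weakly informative priors by blocked Gibbs
    sampling, and summarizes posteriors with highest-density intervals,
    probability of direction, standardized effects, and marginal/conditional
    R-squared. Includes posterior-predictive average marginal effects for
    factor contrasts, Pareto-smoothed importance-sampling leave-one-out
    cross-validation with exhaustive interaction-model sweeps, and a synthetic
    data generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    knitr
Config/testthat/edition: 3
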