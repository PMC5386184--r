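Package: teacast
Title: Temporal Expert Advice for Online Forecasting of Short Biomarker Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Online prediction with expert advice for unstable time series,
    including an exponentially recency-weighted variant (temporal expert
    advice) that emphasises near-past performance when weighting experts.
    Provides the weighting engines (standard exponentially weighted average,
    temporal, and discounted Chernov-Zhdanov forecasters), regret upper
    bounds with bound-optimal learning rates, predictive distributions as
    weighted Gaussian mixtures with quantile extraction, expert construction
    from sliding windows over a time-series database or from a piecewise
    linear model of prostate cancer cell dynamics fitted to short PSA
    series, chaotic map simulators (Henon, Ikeda), baseline predictors with
    pairwise win-count tournaments and exact binomial significance
    thresholds, and seed-controlled synthetic data generators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
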