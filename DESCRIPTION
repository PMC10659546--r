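Package: fragmetrics
Title: Rest-Activity Fragmentation Metrics for Epoch-Level Accelerometer Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes circadian rest-activity fragmentation metrics from
    epoch-level accelerometer time series: inter-daily stability (IS) and
    intradaily variability (IV) on hourly activity proportions with an AR(1)
    autocorrelation diagnostic, maximum-likelihood, Bayesian (Beta-Binomial),
    heuristic and reciprocal-average-duration estimators of rest/activity
    transition probabilities (order-1, duration-dependent, weighted summary,
    and split by awake/sleep windows), detrended fluctuation analysis with
    the self-similarity exponent, and the activity balance index.  Includes
    seed-deterministic generators for AR(1) hourly series, two-state Markov
    and semi-Markov state sequences, white/fractal/brown noise, and a
    realistic seven-day activity profile, so every estimator can be
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
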