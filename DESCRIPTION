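Package: nof1steps
Title: Personalized (N-of-1) Trial Analysis of Wearable Step-Count Data
Version: 0.1.0
Authors@R:
    person("nof1steps", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for personalized (N-of-1) crossover trials
    whose outcome is a daily step count measured by a wrist-worn activity
    tracker. Infers device wear status from heart-rate presence, imputes
    non-wear minutes with per-minute Poisson log-linear models smoothed by a
    penalized spline, estimates within-subject treatment effects on daily
    totals by feasible generalized least squares under AR(1) errors, and
    summarizes heterogeneity across participants with effect-classification
    counts and inverse-variance pooled forest tables. Includes a synthetic
    Fitbit-like data generator with known ground truth, so every stage is
    testable without trial data, plus a command-line driver and a static
    report renderer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
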