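Package: casim
Title: Constrained Additive Single-Index Models for Cumulative Exposure
    Effects on Health Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits an additive single-index regression model for daily
    health-outcome counts in which each pollutant or weather covariate
    acts through a weighted average of its recent history (a distributed
    lag), with lag weights constrained to the ordered unit simplex and
    effect curves estimated by constrained cubic B-spline regression.
    Includes day-of-week effects, a logistic growth-curve term for a
    sustained intervention-driven level shift, backfitting estimation,
    AIC-based selection of per-covariate lag lengths, residual-bootstrap
    confidence bounds, and a synthetic-data generator with known truth
    for validating every estimation stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    pracma,
    splines,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
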