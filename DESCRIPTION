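Package: rrml
Title: Robust and Resilient Regression for Scenario-Based Production Forecasting
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Fits basis-expansion forecasts to scenario-indexed time series by
    minimizing a conservativity-weighted combination of the mean absolute
    deviation and a confidence-scaled dispersion of errors across scenarios
    (the RRMAD objective), with per-scenario resiliency coefficients scaling
    the fitted trend into each scenario forecast. The nested absolute values
    are reformulated exactly as a linear program via nonnegative variable
    splitting and solved with a built-in two-phase revised simplex. Includes
    scenario-weighted goodness of fit, closed-form model-size accounting,
    polynomial and sinusoidal basis families, degree-scan / basis-comparison /
    one-parameter sensitivity drivers, a synthetic scenario-series generator
    with known ground truth, delimited-text readers and writers, MPS export,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    quantreg,
    withr,
    jsonlite
Config/testthat/edition: 3
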