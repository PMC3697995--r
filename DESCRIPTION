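Package: spcmort
Title: Statistical Process Control for Risk-Adjusted ICU Mortality Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for monitoring monthly intensive-care mortality series with
    control charts when the data-generating process is autocorrelated, seasonal
    and volatile. Provides synthetic patient-level cohort and structured
    time-series generators, random-coefficient logistic risk adjustment,
    monthly series construction with eligibility screens, time-series
    diagnostics (correlograms, portmanteau and cumulative-periodogram
    white-noise tests, augmented Dickey-Fuller unit-root test, classical
    seasonal decomposition), sparse-lag seasonal ARMA and GARCH estimation,
    EWMA-family control charts (fixed, time-varying, moving centre-line,
    risk-adjusted reference and residual/forecast-error charts), and
    average-run-length based chart design via Markov-chain and Monte-Carlo
    computation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    lme4,
    MASS,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
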