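Package: itsarima
Title: Interrupted Time Series Analysis with Seasonal ARIMA Intervention Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for evaluating large-scale health interventions with
    interrupted time series (ITS) designs based on seasonal ARIMA models.
    Provides calendar-aware monthly and quarterly series handling,
    differencing, correlograms and unit-root testing; step, pulse and ramp
    intervention inputs with rational (Box-Jenkins) transfer functions;
    exact Gaussian maximum-likelihood estimation of seasonal ARIMA models
    with intervention regressors via a state-space prediction-error
    decomposition; stepwise information-criterion order search; Ljung-Box
    and normality residual diagnostics; and counterfactual effect
    estimation with delta-method confidence intervals. Includes a
    synthetic-data generator emulating monthly dispensing claims with
    end-of-year stockpiling seasonality, and a command-line interface for
    reproducible analysis runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
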