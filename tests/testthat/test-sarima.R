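test_that("order construction enforces the model-family constraints", {
  o <- arima_order(2, 1, 0, P = 0, D = 1, Q = 1, s = 12)
  expect_identical(format(o), "(2,1,0)(0,1,1)[12]")
  expect_error(arima_order(1, 2, 0, D = 2, s = 12), "d \\+ D")
  expect_error(arima_order(1, 0, 0, P = 1, s = 1), "s = 1")
  expect_error(arima_order(-1, 0, 0), "non-negative")
})

test_that("white-noise fit recovers the sample mean and variance exactly", {
  y <- white_noise(500, seed = 21, mean = 10)
  fit <- sarima_fit(y, arima_order(0, 0, 0, s = 1))
  expect_equal(unname(coef(fit)["intercept"]), mean(y), tolerance = 1e-6)
  expect_equal(fit$sigma2, mean((as.numeric(y) - mean(y))^2),
               tolerance = 1e-6)
  expect_identical(fit$n_effective, 500L)
  expect_length(residuals(fit), 500L)
})

test_that("exact ML agrees with an independent ARIMA implementation", {
  y <- ar1_series(300, phi = 0.5, seed = 22)
  fit <- sarima_fit(y, arima_order(1, 0, 0, s = 1))
  oracle <- stats::arima(as.numeric(y), order = c(1, 0, 0))
  expect_equal(fit$loglik, as.numeric(stats::logLik(oracle)), tolerance = 1e-6)
  expect_equal(unname(coef(fit)["ar1"]), unname(coef(oracle)["ar1"]),
               tolerance = 1e-4)
  expect_equal(unname(fit$se["ar1"]), sqrt(oracle$var.coef["ar1", "ar1"]),
               tolerance = 1e-2)
  expect_equal(fit$aic, stats::AIC(oracle), tolerance = 1e-4)
})

test_that("intervention regressors are differenced with the outcome", {
  fx <- quetiapine_fixture(seed = 2014)
  fit <- suppressWarnings(
    sarima_fit(fx$series, arima_order(2, 1, 0, P = 0, D = 1, Q = 1, s = 12),
               interventions = fx$interventions))
  X <- cbind(step = c(rep(0, 36), rep(1, 12)), ramp = c(rep(0, 36), 1:12))
  oracle <- stats::arima(as.numeric(fx$series), order = c(2, 1, 0),
                         seasonal = list(order = c(0, 1, 1), period = 12),
                         xreg = X)
  expect_equal(fit$loglik, as.numeric(stats::logLik(oracle)), tolerance = 1e-3)
  for (nm in c("ar1", "ar2", "step", "ramp"))
    expect_equal(unname(coef(fit)[nm]), unname(coef(oracle)[nm]),
                 tolerance = 1e-2)
  expect_identical(fit$n_effective, 48L - 1L - 12L)
})

test_that("likelihood at the optimum dominates the truth (optimizer sanity)", {
  for (seed in 1:5) {
    y <- ar1_series(150, phi = 0.55, seed = 300 + seed)
    fit <- sarima_fit(y, arima_order(1, 0, 0, s = 1))
    kal_truth <- itsarima:::arma_kalman(as.numeric(y) - mean(y), 0.55,
                                        numeric(0))
    expect_gte(fit$loglik, kal_truth$loglik - 1e-8)
  }
})

test_that("information criteria are recomputable from loglik and k", {
  y <- ar1_series(200, seed = 23)
  fit <- sarima_fit(y, arima_order(1, 0, 1, s = 1))
  k <- fit$k
  expect_identical(k, 3L + 1L)   # ar1, ma1, intercept + sigma2
  expect_equal(fit$aic, -2 * fit$loglik + 2 * k)
  expect_equal(fit$bic, -2 * fit$loglik + k * log(fit$n_effective))
  expect_equal(fit$aicc,
               fit$aic + 2 * k * (k + 1) / (fit$n_effective - k - 1))
})

test_that("short series and over-parameterised models are rejected", {
  y <- its_series(rnorm(10), frequency = 1)
  expect_error(sarima_fit(y, arima_order(5, 0, 5, s = 1)), "insufficient data")
  yy <- monthly_series(rnorm(13))
  expect_error(sarima_fit(yy, arima_order(0, 1, 0, D = 1, s = 12)),
               "too short")
})

test_that("parameter recovery improves with sample size", {
  rmse <- vapply(c(100, 400, 1600), function(n) {
    err <- vapply(1:12, function(s) {
      y <- ar1_series(n, phi = 0.5, seed = 7000 + 13 * n + s)
      fit <- sarima_fit(y, arima_order(1, 0, 0, s = 1))
      unname(coef(fit)["ar1"]) - 0.5
    }, 0)
    sqrt(mean(err^2))
  }, 0)
  expect_lt(rmse[2], rmse[1])
  expect_lt(rmse[3], rmse[2])
  expect_lt(rmse[3], 0.05)
})

# ---- simulation --------------------------------------------------------------

test_that("simulator honours mean, variance and the seed contract", {
  y <- simulate_sarima(arima_order(0, 0, 0), constant = 10, n = 10000,
                       seed = 31)
  expect_equal(mean(y), 10, tolerance = 0.05)

  v <- stats::var(as.numeric(simulate_sarima(arima_order(1, 0, 0), phi = 0.6,
                                             n = 20000, seed = 32)))
  expect_equal(v, 1 / (1 - 0.36), tolerance = 0.05 * 1.5625)

  a <- simulate_sarima(arima_order(1, 0, 0), phi = 0.4, n = 50, seed = 5)
  b <- simulate_sarima(arima_order(1, 0, 0), phi = 0.4, n = 50, seed = 5)
  c2 <- simulate_sarima(arima_order(1, 0, 0), phi = 0.4, n = 50, seed = 6)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_false(identical(as.numeric(a), as.numeric(c2)))

  expect_error(simulate_sarima(arima_order(1, 0, 0), phi = 1.05, n = 50),
               "unstable")
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(simulate_sarima(arima_order(1, 0, 0), phi = 0.5, n = 30, seed = 1))
  after <- rnorm(1)
  expect_identical(before, after)
})

# ---- forecasting -------------------------------------------------------------

test_that("constant-model forecasts are flat with constant-width intervals", {
  y <- white_noise(400, seed = 41, mean = 5)
  fit <- sarima_fit(y, arima_order(0, 0, 0, s = 1))
  fc <- predict(fit, horizon = 6)
  expect_equal(fc$forecast, rep(unname(coef(fit)["intercept"]), 6),
               tolerance = 1e-10)
  expect_equal(fc$upper - fc$forecast,
               rep(1.96 * sqrt(fit$sigma2), 6), tolerance = 1e-3)
})

test_that("AR(1) forecasts follow the closed-form recursion", {
  y <- ar1_series(300, phi = 0.6, seed = 42, mean = 3)
  fit <- sarima_fit(y, arima_order(1, 0, 0, s = 1))
  mu <- unname(coef(fit)["intercept"])
  phi <- unname(coef(fit)["ar1"])
  fc <- predict(fit, horizon = 8)
  closed <- mu + phi^(1:8) * (as.numeric(y)[300] - mu)
  expect_equal(fc$forecast, closed, tolerance = 1e-6)
  # forecast-error variance: sigma2 * sum(phi^(2j))
  expect_equal(fc$se^2,
               fit$sigma2 * cumsum(phi^(2 * (0:7))), tolerance = 1e-6)
})

test_that("prediction-interval width is non-decreasing in the horizon", {
  fx <- quetiapine_fixture(seed = 7)
  fit <- suppressWarnings(
    sarima_fit(fx$series, arima_order(1, 1, 0, P = 0, D = 1, Q = 1, s = 12),
               interventions = fx$interventions))
  fc <- predict(fit, horizon = 24)
  widths <- fc$upper - fc$lower
  expect_true(all(diff(widths) > -1e-8))
  expect_identical(fc$date[1], "2015-01")
})
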