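test_that("series construction validates values, spacing and period", {
  y <- its_series(1:24, start = c(2011, 1), frequency = 12, label = "x")
  expect_s3_class(y, "its_series")
  expect_identical(length(y), 24L)
  expect_identical(period_labels(y)[1], "2011-01")
  expect_identical(period_labels(y)[13], "2012-01")

  expect_error(its_series(c(1, NA, 3)), "finite")
  expect_error(its_series(c(1, Inf)), "finite")
  expect_error(its_series(numeric(0)), "length")
  expect_error(its_series(1:5, frequency = 0), "period")

  q <- its_series(1:8, start = "2011-Q1", frequency = 4)
  expect_identical(period_labels(q)[5], "2012-Q1")
  expect_error(parse_period("2011-13", 12), "range")
  expect_error(parse_period("2011-03", 4), "frequency")
})

test_that("differencing matches its definition and bookkeeping", {
  expect_equal(as.numeric(difference(its_series(c(5, 5, 5, 5), frequency = 1),
                                     lag = 1)),
               c(0, 0, 0))
  expect_equal(as.numeric(difference(its_series(1:5, frequency = 1), lag = 1)),
               rep(1, 4))

  # one full seasonal pattern repeated: seasonal difference is all zero and
  # the first year of observations is lost
  pat <- monthly_series(rep(sin(2 * pi * (1:12) / 12) * 5 + 10, 2))
  dz <- difference(pat, lag = 12)
  expect_equal(as.numeric(dz), rep(0, 12))
  expect_identical(length(dz), 24L - 12L)
  expect_identical(period_labels(dz)[1], "2012-01")

  expect_error(difference(its_series(1:5, frequency = 1), lag = 5),
               "insufficient observations.*6")
})

test_that("difference operators commute", {
  y <- monthly_series(as.numeric(white_noise(60, seed = 4)) + 1:60)
  a <- difference(difference(y, lag = 1), lag = 12)
  b <- difference(difference(y, lag = 12), lag = 1)
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-12)
  expect_identical(stats::start(a), stats::start(b))
})

test_that("log transform is recorded, inverts, and rejects non-positive input", {
  y <- its_series(c(1, exp(1), exp(2)), frequency = 1)
  ly <- log_transform(y)
  expect_equal(as.numeric(ly), c(0, 1, 2))
  expect_identical(attr(ly, "transform"), "log")
  expect_error(log_transform(its_series(c(1, 0, 2), frequency = 1)),
               "strictly positive")
  z <- its_series(runif(50, 1, 100), frequency = 4)
  expect_equal(exp(as.numeric(log_transform(z))), as.numeric(z),
               tolerance = 1e-12)
})

test_that("ACF is the biased correlogram estimator with white-noise band", {
  y <- ar1_series(300, seed = 2)
  cg <- correlogram(y, max_lag = 20, type = "acf")
  expect_equal(cg$value[cg$lag == 0], 1)
  expect_true(all(cg$value >= -1 & cg$value <= 1))
  expect_equal(attr(cg, "ci_bound"), 1.96 / sqrt(300))
  # denominator convention: matches the standard biased estimator
  v <- as.numeric(y) - mean(y)
  r5 <- sum(v[1:295] * v[6:300]) / sum(v^2)
  expect_equal(cg$value[cg$lag == 5], r5, tolerance = 1e-12)
  expect_error(correlogram(y, max_lag = 300), "smaller than the series length")
})

test_that("ACF of a long AR(1) simulation follows phi^k", {
  y <- ar1_series(5000, phi = 0.6, seed = 11)
  cg <- correlogram(y, max_lag = 5, type = "acf")
  expect_equal(cg$value[cg$lag %in% 1:5], 0.6^(1:5), tolerance = 0.05)
})

test_that("white-noise ACF stays inside the significance band ~95% of lags", {
  inside <- vapply(1:10, function(s) {
    y <- white_noise(2000, seed = 100 + s)
    cg <- correlogram(y, max_lag = 20, type = "acf")
    mean(abs(cg$value[cg$lag >= 1]) < attr(cg, "ci_bound"))
  }, 0)
  expect_gt(mean(inside), 0.90)
})

test_that("PACF matches theory: lag-1 equals ACF, AR(1) cuts off, MA(1) tails", {
  y <- ar1_series(5000, phi = 0.6, seed = 12)
  pa <- correlogram(y, max_lag = 8, type = "pacf")
  ac <- correlogram(y, max_lag = 8, type = "acf")
  expect_equal(pa$value[pa$lag == 1], ac$value[ac$lag == 1], tolerance = 1e-12)
  expect_equal(pa$value[pa$lag == 1], 0.6, tolerance = 0.05)
  expect_true(all(abs(pa$value[pa$lag >= 2]) < 0.05))

  # MA(1): ACF cuts off after lag 1 while the PACF tails off
  ym <- simulate_sarima(arima_order(0, 0, 1), theta = 0.7, n = 5000, seed = 13)
  acm <- correlogram(ym, max_lag = 6, type = "acf")
  pam <- correlogram(ym, max_lag = 6, type = "pacf")
  expect_gt(acm$value[acm$lag == 1], 0.35)
  expect_true(all(abs(acm$value[acm$lag >= 2]) < 0.06))
  expect_gt(abs(pam$value[pam$lag == 2]), 0.06)
})

test_that("Durbin-Levinson equals the definitional normal-equations solution", {
  for (seed in 1:6) {
    y <- if (seed %% 2) ar1_series(150 + seed * 10, phi = 0.5, seed = seed)
      else simulate_sarima(arima_order(0, 0, 1), theta = 0.6,
                           n = 120 + seed * 10, seed = seed)
    pa <- correlogram(y, max_lag = 5, type = "pacf")
    for (k in 1:5)
      expect_equal(pa$value[pa$lag == k], pacf_by_regression(y, k),
                   tolerance = 1e-10)
  }
})

test_that("ADF test distinguishes random walks from stationary noise", {
  rw_reject <- vapply(1:50, function(s) {
    y <- its_series(cumsum(as.numeric(white_noise(500, seed = 2000 + s))),
                    frequency = 1)
    adf_test(y)$reject_unit_root
  }, TRUE)
  wn_reject <- vapply(1:50, function(s) {
    adf_test(white_noise(500, seed = 3000 + s))$reject_unit_root
  }, TRUE)
  expect_lte(mean(rw_reject), 0.10)   # size under the unit-root null
  expect_gte(mean(wn_reject), 0.90)   # power under a stationary alternative

  expect_error(adf_test(its_series(rep(3, 50), frequency = 1)), "constant")
  expect_error(adf_test(white_noise(8)), "too short")
})

test_that("CSV round trip preserves the series; gaps and bad columns error", {
  y <- monthly_series(round(runif(30, 50, 150), 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_series_csv(y, path)
  y2 <- read_series_csv(path)
  expect_equal(as.numeric(y2), as.numeric(y))
  expect_identical(stats::start(y2), stats::start(y))
  expect_equal(stats::frequency(y2), 12)

  df <- utils::read.csv(path)
  utils::write.csv(df[-5, ], path, row.names = FALSE)
  expect_error(read_series_csv(path), "gap or duplicate")
  expect_error(read_series_csv(path, value_col = "nope"), "not found")
})

test_that("correlogram CSV export carries lag, value and band", {
  y <- ar1_series(100, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_correlogram_csv(correlogram(y, 10), path)
  df <- utils::read.csv(path)
  expect_named(df, c("lag", "value", "ci_bound"))
  expect_equal(df$ci_bound[1], 1.96 / sqrt(100))
})
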