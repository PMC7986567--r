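# small simulation helpers shared across test files

ar1_series <- function(n, phi = 0.6, sd = 1, seed = 1, mean = 0) {
  simulate_sarima(arima_order(1, 0, 0), phi = phi, n = n, sd = sd,
                  seed = seed, constant = mean)
}

white_noise <- function(n, seed = 1, mean = 0, sd = 1) {
  simulate_sarima(arima_order(0, 0, 0), n = n, sd = sd, seed = seed,
                  constant = mean)
}

monthly_series <- function(values, start = c(2011, 1)) {
  its_series(values, start = start, frequency = 12)
}

# brute-force PACF at lag k: last coefficient of an OLS regression of
# Y_t on Y_{t-1}..Y_{t-k} (the definitional oracle for Durbin-Levinson)
pacf_by_regression <- function(x, k) {
  v <- as.numeric(x) - mean(x)
  n <- length(v)
  X <- sapply(1:k, function(j) v[(k + 1 - j):(n - j)])
  resp <- v[(k + 1):n]
  # regression on sample-autocorrelation (Yule-Walker) normal equations so
  # the estimator matches the Durbin-Levinson input exactly
  r <- as.numeric(stats::acf(v, lag.max = k, plot = FALSE, demean = FALSE)$acf)
  R <- stats::toeplitz(r[1:k])
  drop(solve(R, r[2:(k + 1)]))[k]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
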