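#' Ljung-Box portmanteau test for residual white noise
#'
#' Tests the joint null that the first `lags` autocorrelations of a
#' residual series are zero:
#' `Q = n (n + 2) * sum_{k=1..L} r_k^2 / (n - k)`, referred to a
#' chi-squared distribution with `lags - fitdf` degrees of freedom. When
#' applied to residuals of a fitted ARMA model, `fitdf` should count the
#' estimated ARMA terms (`p + q + P + Q`); the constant and the innovation
#' variance are not counted, following the dominant convention.
#'
#' @param x residual series (`its_series`, `ts` or numeric), or a
#'   `sarima_fit` (its residuals are used and `fitdf` defaults to the
#'   model's `p + q + P + Q`).
#' @param lags number of autocorrelations in the statistic; defaults to
#'   `min(24, n/2)`.
#' @param fitdf degrees of freedom consumed by fitting (default 0 for a raw
#'   series).
#' @return list of class `ljung_box` with `statistic`, `df`, `p_value`,
#'   `lags`, `fitdf`, `n`.
#' @examples
#' set.seed(1)
#' ljung_box(rnorm(200), lags = 10)
#' @export
ljung_box <- function(x, lags = NULL, fitdf = 0L) {
  if (inherits(x, "sarima_fit")) {
    if (missing(fitdf))
      fitdf <- x$order$p + x$order$q + x$order$P + x$order$Q
    x <- x$residuals
  }
  v <- as.numeric(x)
  n <- length(v)
  if (is.null(lags)) lags <- min(24L, floor(n / 2))
  lags <- as.integer(lags); fitdf <- as.integer(fitdf)
  if (lags >= n) stop("'lags' must be smaller than the series length", call. = FALSE)
  if (lags <= fitdf)
    stop("degrees of freedom must be positive: 'lags' must exceed 'fitdf'",
         call. = FALSE)
  r <- as.numeric(stats::acf(v, lag.max = lags, plot = FALSE)$acf)[-1L]
  Q <- n * (n + 2) * sum(r^2 / (n - seq_len(lags)))
  df <- lags - fitdf
  structure(list(statistic = Q, df = df,
                 p_value = stats::pchisq(Q, df, lower.tail = FALSE),
                 lags = lags, fitdf = fitdf, n = n),
            class = "ljung_box")
}

#' @export
print.ljung_box <- function(x, ...) {
  cat(sprintf("Ljung-Box test: Q = %.3f on %d df (%d lags, fitdf = %d), p = %.4f\n",
              x$statistic, x$df, x$lags, x$fitdf, x$p_value))
  invisible(x)
}

#' Jarque-Bera normality test
#'
#' `JB = n/6 * (skewness^2 + (kurtosis - 3)^2 / 4)`, chi-squared with 2 df
#' under normality.
#'
#' @param x numeric vector (or `ts`).
#' @return list with `statistic`, `p_value`, `skewness`, `kurtosis`.
#' @export
jarque_bera <- function(x) {
  v <- as.numeric(x)
  n <- length(v)
  if (n < 4L) stop("need at least 4 observations", call. = FALSE)
  m <- mean(v)
  s2 <- mean((v - m)^2)
  skew <- mean((v - m)^3) / s2^1.5
  kurt <- mean((v - m)^4) / s2^2
  jb <- n / 6 * (skew^2 + (kurt - 3)^2 / 4)
  list(statistic = jb, p_value = stats::pchisq(jb, 2, lower.tail = FALSE),
       skewness = skew, kurtosis = kurt)
}

#' Residual diagnostics report for a fitted model
#'
#' Bundles the standard white-noise checks on a model's one-step
#' innovations: mean and variance, residual ACF with its significance band,
#' the Ljung-Box portmanteau test (`fitdf` set to the model's ARMA term
#' count), and a Jarque-Bera normality check. The overall verdict is
#' `"pass"` when the Ljung-Box test does not reject white noise at
#' `alpha` — the decision rule under which a candidate model is accepted as
#' adequately capturing the autocorrelation.
#'
#' @param model a `sarima_fit`.
#' @param lags Ljung-Box lags; defaults to `min(24, n_effective / 2)`.
#' @param alpha significance level for the verdict.
#' @return list of class `its_residual_report`.
#' @export
residual_report <- function(model, lags = NULL, alpha = 0.05) {
  stopifnot(inherits(model, "sarima_fit"))
  res <- as.numeric(model$residuals)
  n <- length(res)
  if (is.null(lags)) lags <- min(24L, floor(n / 2))
  fitdf <- model$order$p + model$order$q + model$order$P + model$order$Q
  if (lags <= fitdf) lags <- fitdf + 1L
  lb <- ljung_box(model$residuals, lags = lags, fitdf = fitdf)
  acf_tab <- correlogram(model$residuals,
                         max_lag = min(lags, n - 1L), type = "acf")
  nb <- jarque_bera(res)
  rep <- list(residual_mean = mean(res),
              residual_variance = stats::var(res),
              acf = acf_tab,
              ljung_box = lb,
              normality = nb,
              alpha = alpha,
              verdict = if (lb$p_value > alpha) "pass" else "fail")
  class(rep) <- "its_residual_report"
  rep
}

#' @export
print.its_residual_report <- function(x, ...) {
  cat("Residual diagnostics\n")
  cat(sprintf("  mean %.4g, variance %.4g\n", x$residual_mean,
              x$residual_variance))
  cat(sprintf("  Ljung-Box: Q = %.3f on %d df, p = %.4f\n",
              x$ljung_box$statistic, x$ljung_box$df, x$ljung_box$p_value))
  cat(sprintf("  Jarque-Bera: %.3f, p = %.4f\n", x$normality$statistic,
              x$normality$p_value))
  cat(sprintf("  verdict at alpha = %.2f: %s (white-noise residuals %s)\n",
              x$alpha, x$verdict,
              if (x$verdict == "pass") "not rejected" else "rejected"))
  invisible(x)
}

#' Serialise a residual report to JSON
#' @param report an `its_residual_report`.
#' @param path optional output file.
#' @return the list form (invisibly when writing).
#' @export
residual_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "its_residual_report"))
  out <- list(
    residual_mean = report$residual_mean,
    residual_variance = report$residual_variance,
    ljung_box = unclass(report$ljung_box),
    normality = report$normality,
    acf = list(lag = report$acf$lag, value = report$acf$value,
               ci_bound = attr(report$acf, "ci_bound")),
    alpha = report$alpha,
    verdict = report$verdict
  )
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(out))
  }
  out
}
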