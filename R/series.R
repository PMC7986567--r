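#' Construct an interrupted-time-series object
#'
#' An `its_series` is a univariate, equally spaced, calendar-aware time
#' series: a thin layer over [stats::ts()] that enforces the assumptions of
#' seasonal ARIMA modelling at construction time (finite values, no gaps,
#' declared seasonal period) and carries a label plus a record of any
#' variance-stabilising transform.
#'
#' @param values numeric vector of observations (counts or rates); must be
#'   finite — missing values are rejected, not imputed.
#' @param start calendar period of the first observation: either a
#'   `c(year, cycle)` pair (e.g. `c(2011, 1)` for January 2011 at monthly
#'   frequency) or a period string such as `"2011-01"` (monthly) or
#'   `"2011-Q1"` (quarterly).
#' @param frequency seasonal period `s`: observations per seasonal cycle
#'   (12 for monthly, 4 for quarterly, 1 for non-seasonal).
#' @param label free-text description used in printing and reports.
#' @return an object of class `c("its_series", "ts")`.
#' @examples
#' y <- its_series(rpois(24, 100), start = c(2011, 1), frequency = 12,
#'                 label = "monthly dispensings")
#' period_labels(y)[1:3]
#' @export
its_series <- function(values, start = c(1, 1), frequency = 12, label = "") {
  if (!is.numeric(values) || length(values) < 1L)
    stop("'values' must be a numeric vector of length >= 1", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("series values must all be finite; missing values are not supported",
         call. = FALSE)
  frequency <- as.integer(frequency)
  if (is.na(frequency) || frequency < 1L)
    stop("'frequency' (seasonal period) must be an integer >= 1", call. = FALSE)
  if (is.character(start)) start <- parse_period(start, frequency)
  x <- stats::ts(as.numeric(values), start = start, frequency = frequency)
  attr(x, "label") <- as.character(label)[1L]
  attr(x, "transform") <- "none"
  class(x) <- c("its_series", "ts")
  x
}

#' Coerce a `ts` (or numeric vector) to an `its_series`
#'
#' @param x a `ts` object or numeric vector.
#' @param ... passed to [its_series()] when `x` is a bare vector.
#' @return an `its_series`.
#' @export
as_its_series <- function(x, ...) {
  if (inherits(x, "its_series")) return(x)
  if (stats::is.ts(x)) {
    out <- its_series(as.numeric(x), start = stats::start(x),
                      frequency = stats::frequency(x), ...)
    return(out)
  }
  its_series(x, ...)
}

#' @export
print.its_series <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("its_series: %s\n", if (nzchar(lab)) lab else "<unlabelled>"))
  cat(sprintf("  %d observations, period s = %d, %s to %s\n",
              length(x), stats::frequency(x),
              format_period(stats::start(x), stats::frequency(x)),
              format_period(stats::end(x), stats::frequency(x))))
  if (!identical(attr(x, "transform"), "none"))
    cat(sprintf("  transform: %s\n", attr(x, "transform")))
  y <- x
  attributes(y) <- NULL
  print(stats::ts(y, start = stats::start(x), frequency = stats::frequency(x)),
        ...)
  invisible(x)
}

# ---- calendar period helpers -------------------------------------------------

#' Parse a calendar-period string
#'
#' Accepts `"YYYY-MM"` for monthly series, `"YYYY-Qn"` for quarterly, and a
#' plain `"YYYY"` for annual (frequency 1). Numeric pairs pass through.
#'
#' @param period character period or `c(year, cycle)` pair.
#' @param frequency seasonal period of the target series.
#' @return integer vector `c(year, cycle)`.
#' @export
parse_period <- function(period, frequency) {
  if (is.numeric(period)) {
    if (length(period) == 1L) return(c(as.integer(period), 1L))
    return(as.integer(period[1:2]))
  }
  p <- trimws(as.character(period)[1L])
  if (grepl("^\\d{4}-Q[1-4]$", p, ignore.case = TRUE)) {
    if (frequency != 4L)
      stop(sprintf("quarter period '%s' given but series frequency is %d",
                   p, frequency), call. = FALSE)
    return(c(as.integer(substr(p, 1, 4)),
             as.integer(substr(p, 7, 7))))
  }
  if (grepl("^\\d{4}-\\d{2}$", p)) {
    cyc <- as.integer(substr(p, 6, 7))
    if (frequency != 12L)
      stop(sprintf("month period '%s' given but series frequency is %d",
                   p, frequency), call. = FALSE)
    if (cyc < 1L || cyc > 12L)
      stop(sprintf("month out of range in period '%s'", p), call. = FALSE)
    return(c(as.integer(substr(p, 1, 4)), cyc))
  }
  if (grepl("^\\d{4}$", p)) return(c(as.integer(p), 1L))
  stop(sprintf("cannot parse period '%s' (expected YYYY-MM, YYYY-Qn or YYYY)",
               p), call. = FALSE)
}

#' Format a `c(year, cycle)` period as a string
#' @param period `c(year, cycle)` pair.
#' @param frequency seasonal period.
#' @return character scalar like `"2014-01"`.
#' @export
format_period <- function(period, frequency) {
  y <- period[1L]; c0 <- if (length(period) > 1L) period[2L] else 1L
  if (frequency == 12L) sprintf("%04d-%02d", y, c0)
  else if (frequency == 4L) sprintf("%04d-Q%d", y, c0)
  else if (frequency == 1L) sprintf("%04d", y)
  else sprintf("%04d-%02d", y, c0)
}

#' Calendar labels for each observation of a series
#' @param x a `ts` or `its_series`.
#' @return character vector, one period label per observation.
#' @export
period_labels <- function(x) {
  s <- stats::frequency(x)
  tt <- round(stats::time(x) * s) / s
  yr <- floor(tt + 1e-8)
  cyc <- as.integer(round((tt - yr) * s)) + 1L
  vapply(seq_along(yr), function(i) format_period(c(yr[i], cyc[i]), s), "")
}

#' Index (1-based position) of a calendar period within a series
#' @param x a `ts` or `its_series`.
#' @param period a period string or `c(year, cycle)` pair.
#' @return integer position; may fall outside `1..length(x)` when the period
#'   is outside the observed range.
#' @export
period_index <- function(x, period) {
  s <- stats::frequency(x)
  p <- parse_period(period, s)
  t0 <- stats::start(x)
  as.integer(round((p[1L] - t0[1L]) * s + (p[2L] - t0[2L]))) + 1L
}

# ---- transformations ---------------------------------------------------------

#' Difference a series
#'
#' Computes `Y'_t = Y_t - Y_{t-lag}` applied `times` times. Lag 1 removes a
#' trend (regular differencing, degree `d`); lag equal to the seasonal
#' period removes stable seasonality (seasonal differencing, degree `D`).
#' Each application at lag `k` shortens the series by `k` observations and
#' advances the start period accordingly.
#'
#' @param x an `its_series` (or `ts`).
#' @param lag differencing lag (integer >= 1).
#' @param times number of times to apply the difference.
#' @return a shorter `its_series`.
#' @export
difference <- function(x, lag = 1L, times = 1L) {
  x <- as_its_series(x)
  lag <- as.integer(lag); times <- as.integer(times)
  if (lag < 1L || times < 1L)
    stop("'lag' and 'times' must be integers >= 1", call. = FALSE)
  need <- lag * times + 1L
  if (length(x) < need)
    stop(sprintf(
      "insufficient observations for differencing: need at least %d, have %d",
      need, length(x)), call. = FALSE)
  out <- diff(stats::ts(as.numeric(x), start = stats::start(x),
                        frequency = stats::frequency(x)),
              lag = lag, differences = times)
  res <- its_series(as.numeric(out), start = stats::start(out),
                    frequency = stats::frequency(x), label = attr(x, "label"))
  attr(res, "transform") <- attr(x, "transform")
  res
}

#' Natural-log transform of a strictly positive series
#'
#' Applied when the variance of a series grows with its level
#' (heteroscedasticity); the transform is recorded on the object so that
#' downstream effect estimates can be reported on either scale.
#'
#' @param x an `its_series` with all values > 0.
#' @return the log-scale `its_series`, with `attr(, "transform") == "log"`.
#' @export
log_transform <- function(x) {
  x <- as_its_series(x)
  if (any(as.numeric(x) <= 0))
    stop("log transform requires strictly positive series", call. = FALSE)
  out <- its_series(log(as.numeric(x)), start = stats::start(x),
                    frequency = stats::frequency(x), label = attr(x, "label"))
  attr(out, "transform") <- "log"
  out
}

# ---- correlograms ------------------------------------------------------------

#' Sample autocorrelation / partial autocorrelation function
#'
#' `correlogram()` computes the sample ACF (standard biased estimator:
#' lagged cross-products about the sample mean divided by the lag-0 sum of
#' squares, which keeps the sequence positive semi-definite) or the PACF via
#' the Durbin-Levinson recursion applied to that ACF. The white-noise
#' significance band is the usual `+/- 1.96 / sqrt(n)` dashed-line bound.
#'
#' @param x an `its_series` (or `ts`).
#' @param max_lag largest lag to report; must be `< length(x)`.
#' @param type `"acf"` or `"pacf"`.
#' @return an `its_correlogram`: a data frame with columns `lag` and
#'   `value`, and attributes `ci_bound`, `n` and `type`. The ACF includes
#'   lag 0 (always exactly 1); the PACF starts at lag 1.
#' @export
correlogram <- function(x, max_lag = NULL, type = c("acf", "pacf")) {
  type <- match.arg(type)
  x <- as_its_series(x)
  n <- length(x)
  if (is.null(max_lag))
    max_lag <- min(n - 1L, if (stats::frequency(x) > 1L) 2L * stats::frequency(x) else 20L)
  max_lag <- as.integer(max_lag)
  if (max_lag >= n)
    stop(sprintf("max_lag (%d) must be smaller than the series length (%d)",
                 max_lag, n), call. = FALSE)
  if (max_lag < 1L) stop("'max_lag' must be >= 1", call. = FALSE)
  r <- as.numeric(stats::acf(as.numeric(x), lag.max = max_lag,
                             plot = FALSE, demean = TRUE)$acf)
  if (type == "acf") {
    out <- data.frame(lag = 0:max_lag, value = r)
  } else {
    out <- data.frame(lag = 1:max_lag, value = durbin_levinson(r[-1L]))
  }
  attr(out, "ci_bound") <- 1.96 / sqrt(n)
  attr(out, "n") <- n
  attr(out, "type") <- type
  class(out) <- c("its_correlogram", "data.frame")
  out
}

# Durbin-Levinson: partial autocorrelations phi_{k,k} from acf values r_1..r_L.
durbin_levinson <- function(r) {
  L <- length(r)
  pacf <- numeric(L)
  phi_prev <- numeric(0)
  for (k in seq_len(L)) {
    if (k == 1L) {
      phi_kk <- r[1L]
      phi <- phi_kk
    } else {
      num <- r[k] - sum(phi_prev * r[(k - 1L):1L])
      den <- 1 - sum(phi_prev * r[1:(k - 1L)])
      if (abs(den) < 1e-14)
        stop("Durbin-Levinson recursion degenerate (singular autocorrelation)",
             call. = FALSE)
      phi_kk <- num / den
      phi <- c(phi_prev - phi_kk * rev(phi_prev), phi_kk)
    }
    pacf[k] <- phi_kk
    phi_prev <- phi
  }
  pacf
}

#' @export
print.its_correlogram <- function(x, ...) {
  cat(sprintf("%s (n = %d, white-noise band +/- %.4f)\n",
              toupper(attr(x, "type")), attr(x, "n"), attr(x, "ci_bound")))
  print(as.data.frame(x), row.names = FALSE, ...)
  invisible(x)
}

#' Write a correlogram to CSV
#'
#' Emits columns `lag`, `value`, `ci_bound` — the plot-ready data behind a
#' standard correlogram figure with its dashed significance band.
#'
#' @param x an `its_correlogram`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_correlogram_csv <- function(x, path) {
  stopifnot(inherits(x, "its_correlogram"))
  df <- data.frame(lag = x$lag, value = x$value,
                   ci_bound = attr(x, "ci_bound"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---- augmented Dickey-Fuller unit-root test ---------------------------------

# MacKinnon (1994, 2010) response-surface coefficients for the ADF t-statistic
# p-value, single-series case; constant-only and constant+trend variants.
.adf_surface <- list(
  constant = list(star = -1.61, min = -18.83, max = 2.74,
                  small = c(2.1659, 1.4412, 0.038269),
                  large = c(1.7339, 0.93202, -0.12745, -0.010368)),
  trend = list(star = -2.89, min = -16.18, max = 0.70,
               small = c(3.2512, 1.6047, 0.049588),
               large = c(2.5261, 0.61654, -0.37956, -0.060285))
)

#' Augmented Dickey-Fuller unit-root test
#'
#' Regresses `diff(y)_t` on `y_{t-1}`, lagged differences and deterministic
#' terms, and refers the t-statistic of the `y_{t-1}` coefficient to the
#' MacKinnon response-surface approximation of the Dickey-Fuller
#' distribution. Rejection indicates stationarity (no unit root). The
#' deterministic term is a constant by default; a linear trend can be added.
#'
#' @param x an `its_series` (or `ts`).
#' @param max_lag number of lagged differences, or `"auto"` to choose the
#'   lag order in `0..floor((n-1)^(1/3))` by an information criterion.
#' @param type `"constant"` (default) or `"trend"` (constant + linear trend).
#' @param alpha significance level for the rejection flag.
#' @param lag_criterion criterion for the automatic lag choice: `"aic"`
#'   (default) or `"bic"` (more parsimonious; useful on short series where
#'   extra lags drain the test's power).
#' @return a list of class `its_adf` with `statistic`, `p_value`,
#'   `reject_unit_root`, `lag_order`, `type` and `n`.
#' @export
adf_test <- function(x, max_lag = "auto", type = c("constant", "trend"),
                     alpha = 0.05, lag_criterion = c("aic", "bic")) {
  type <- match.arg(type)
  lag_criterion <- match.arg(lag_criterion)
  y <- as.numeric(as_its_series(x))
  n <- length(y)
  if (stats::var(y) < .Machine$double.eps * max(1, mean(y)^2))
    stop("degenerate input: series is constant, unit-root regression undefined",
         call. = FALSE)
  auto <- identical(max_lag, "auto")
  max_cand <- if (auto) max(0L, as.integer(trunc((n - 1)^(1/3)))) else
    as.integer(max_lag)
  if (n < 10L + max_cand)
    stop(sprintf("series too short for ADF test: need >= %d observations, have %d",
                 10L + max_cand, n), call. = FALSE)

  fit_one <- function(k) {
    dy <- diff(y)
    # common sample across candidate lags is not required here: each k is
    # fitted on its own maximal sample, AIC compared on the shared tail
    idx <- (max_cand + 1L):length(dy)   # shared effective sample for AIC
    resp <- dy[idx]
    ylag <- y[idx]
    X <- cbind(intercept = 1, ylag = ylag)
    if (type == "trend") X <- cbind(X, trend = idx)
    if (k > 0L)
      for (j in 1:k) X <- cbind(X, dy[idx - j])
    f <- stats::lm.fit(X, resp)
    rss <- sum(f$residuals^2)
    m <- length(idx)
    pen <- if (lag_criterion == "bic") log(m) else 2
    aic <- m * log(rss / m) + pen * ncol(X)
    tstat <- {
      s2 <- rss / (m - ncol(X))
      XtXi <- chol2inv(chol(crossprod(X)))
      f$coefficients["ylag"] / sqrt(s2 * XtXi[2L, 2L])
    }
    list(aic = aic, tstat = unname(tstat), k = k)
  }

  ks <- if (auto) 0:max_cand else max_cand
  fits <- lapply(ks, fit_one)
  best <- fits[[which.min(vapply(fits, `[[`, 0, "aic"))]]

  su <- .adf_surface[[if (type == "constant") "constant" else "trend"]]
  st <- best$tstat
  p <- if (st > su$max) 1
  else if (st < su$min) 0
  else {
    co <- if (st <= su$star) su$small else su$large
    stats::pnorm(sum(co * st^(seq_along(co) - 1L)))
  }
  structure(list(statistic = st, p_value = p,
                 reject_unit_root = p < alpha, lag_order = best$k,
                 type = type, n = n),
            class = "its_adf")
}

#' @export
print.its_adf <- function(x, ...) {
  cat(sprintf(
    "Augmented Dickey-Fuller test (%s, %d lagged differences, n = %d)\n",
    x$type, x$lag_order, x$n))
  cat(sprintf("  tau = %.4f, p = %.4f -> %s\n", x$statistic, x$p_value,
              if (x$reject_unit_root) "reject unit root (stationary)"
              else "cannot reject unit root (non-stationary)"))
  invisible(x)
}

# ---- CSV I/O -----------------------------------------------------------------

#' Read a two-column date/value CSV as an `its_series`
#'
#' The file must have a header and contain one period column (values such as
#' `"2011-01"` or `"2011-Q1"`) and one numeric column. Frequency is inferred
#' from the period format unless given. Periods must be consecutive: any gap
#' or duplicate is an error, as the models assume equally spaced data.
#'
#' @param path CSV file path.
#' @param date_col,value_col column names (defaults `"date"`, `"value"`).
#' @param frequency optional override of the inferred seasonal period.
#' @param label label for the resulting series (defaults to the file name).
#' @return an `its_series`.
#' @export
read_series_csv <- function(path, date_col = "date", value_col = "value",
                            frequency = NULL, label = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c(date_col, value_col))
    if (!col %in% names(df))
      stop(sprintf("column '%s' not found in %s (columns: %s)", col, path,
                   paste(names(df), collapse = ", ")), call. = FALSE)
  dates <- as.character(df[[date_col]])
  vals <- df[[value_col]]
  if (!is.numeric(vals))
    stop(sprintf("column '%s' is not numeric", value_col), call. = FALSE)
  if (is.null(frequency)) {
    frequency <- if (all(grepl("^\\d{4}-Q[1-4]$", dates))) 4L
    else if (all(grepl("^\\d{4}-\\d{2}$", dates))) 12L
    else if (all(grepl("^\\d{4}$", dates))) 1L
    else stop("cannot infer frequency: dates must all be YYYY-MM, YYYY-Qn or YYYY",
              call. = FALSE)
  }
  periods <- lapply(dates, parse_period, frequency = frequency)
  idx <- vapply(periods, function(p)
    (p[1L] - periods[[1L]][1L]) * frequency + (p[2L] - periods[[1L]][2L]), 0)
  if (!identical(as.integer(idx), seq_along(idx) - 1L))
    stop("dates are not consecutive equally spaced periods (gap or duplicate detected)",
         call. = FALSE)
  its_series(vals, start = periods[[1L]], frequency = frequency,
             label = if (is.null(label)) basename(path) else label)
}

#' Write an `its_series` to CSV
#' @param x an `its_series`.
#' @param path output path.
#' @param date_col,value_col column names to use.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(x, path, date_col = "date", value_col = "value") {
  x <- as_its_series(x)
  df <- data.frame(period_labels(x), as.numeric(x))
  names(df) <- c(date_col, value_col)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
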