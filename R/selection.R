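#' Stepwise automatic SARIMA order search
#'
#' Searches for the `(p, d, q)(P, D, Q)_s` order minimising an information
#' criterion under the usual constraints (`p, q <= 5`, `P, Q <= 2` by
#' default). The search is stepwise: a small set of seed orders is fitted,
#' then all neighbours differing by one in a single order component are
#' evaluated repeatedly until no neighbour improves the criterion (a local
#' minimum). Orders whose fit fails to converge are skipped and logged in
#' the trace. Ties are broken towards parsimony: fewer total parameters,
#' then lower `q`, then lower `p`. Deterministic given the data and
#' configuration.
#'
#' @param series an `its_series` (or `ts`).
#' @param d,D differencing degrees, fixed by the analyst (use
#'   [choose_differencing()] for a data-driven recommendation).
#' @param interventions list of [intervention()] specs passed to every fit.
#' @param criterion `"aicc"` (default, small-sample corrected), `"aic"` or
#'   `"bic"`.
#' @param max_p,max_q,max_P,max_Q search caps.
#' @param include_constant passed to [sarima_fit()].
#' @return a list of class `sarima_search`: `best` (the fitted
#'   `sarima_fit`), `order`, `criterion`, and `trace` (a data frame of every
#'   order tried with its criterion value and convergence flag).
#' @export
auto_sarima <- function(series, d = 0L, D = 0L, interventions = list(),
                        criterion = c("aicc", "aic", "bic"),
                        max_p = 5L, max_q = 5L, max_P = 2L, max_Q = 2L,
                        include_constant = NULL) {
  criterion <- match.arg(criterion)
  series <- as_its_series(series)
  s <- stats::frequency(series)
  if (s == 1L) { max_P <- 0L; max_Q <- 0L }
  d <- as.integer(d); D <- as.integer(D)

  cache <- new.env(parent = emptyenv())
  trace <- list()
  eval_order <- function(p, q, P, Q) {
    key <- paste(p, q, P, Q, sep = ".")
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- tryCatch({
      ord <- arima_order(p, d, q, P = P, D = D, Q = Q, s = s)
      fit <- sarima_fit(series, ord, interventions = interventions,
                        include_constant = include_constant)
      list(fit = fit, crit = fit[[criterion]], converged = TRUE)
    }, error = function(e) list(fit = NULL, crit = Inf, converged = FALSE,
                                msg = conditionMessage(e)))
    trace[[length(trace) + 1L]] <<- data.frame(
      p = p, q = q, P = P, Q = Q, converged = res$converged,
      criterion = if (is.finite(res$crit)) res$crit else NA_real_)
    cache[[key]] <- res
    res
  }

  reg_seeds <- list(c(0, 0), c(1, 0), c(0, 1), c(2, 2))
  seas_seeds <- if (s > 1L) list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
    else list(c(0, 0))
  seeds <- list()
  for (rs in reg_seeds) for (ss in seas_seeds)
    seeds[[length(seeds) + 1L]] <- c(rs, ss)
  seeds <- lapply(seeds, function(v)
    pmin(v, c(max_p, max_q, max_P, max_Q)))

  better <- function(a, b) {
    # a, b: list(crit, p, q, P, Q); TRUE when a strictly preferred over b
    if (is.null(b)) return(TRUE)
    if (!is.finite(a$crit)) return(FALSE)
    if (!is.finite(b$crit)) return(TRUE)
    if (abs(a$crit - b$crit) > 1e-8) return(a$crit < b$crit)
    ka <- a$p + a$q + a$P + a$Q; kb <- b$p + b$q + b$P + b$Q
    if (ka != kb) return(ka < kb)
    if (a$q != b$q) return(a$q < b$q)
    a$p < b$p
  }

  best <- NULL
  for (sv in unique(seeds)) {
    res <- eval_order(sv[1], sv[2], sv[3], sv[4])
    cand <- list(crit = res$crit, p = sv[1], q = sv[2], P = sv[3], Q = sv[4],
                 fit = res$fit)
    if (res$converged && better(cand, best)) best <- cand
  }
  if (is.null(best))
    stop(paste0("no seed model converged; trace:\n",
                paste(utils::capture.output(print(do.call(rbind, trace))),
                      collapse = "\n")), call. = FALSE)

  # moves: +/-1 in a single order, plus joint +/-1 moves on (p, q) and on
  # (P, Q) — the latter let the search cross the ridge between AR-heavy and
  # MA-heavy representations of similar correlation structure
  deltas <- list(c(1, 0, 0, 0), c(-1, 0, 0, 0), c(0, 1, 0, 0), c(0, -1, 0, 0),
                 c(0, 0, 1, 0), c(0, 0, -1, 0), c(0, 0, 0, 1), c(0, 0, 0, -1),
                 c(1, 1, 0, 0), c(-1, -1, 0, 0), c(1, -1, 0, 0), c(-1, 1, 0, 0),
                 c(0, 0, 1, 1), c(0, 0, -1, -1), c(0, 0, 1, -1), c(0, 0, -1, 1))
  caps <- c(max_p, max_q, max_P, max_Q)
  try_move <- function(nb) {
    if (any(nb < 0L) || any(nb > caps)) return(FALSE)
    res <- eval_order(nb[1], nb[2], nb[3], nb[4])
    if (!res$converged) return(FALSE)
    cand <- list(crit = res$crit, p = nb[1], q = nb[2], P = nb[3],
                 Q = nb[4], fit = res$fit)
    if (better(cand, best)) { best <<- cand; return(TRUE) }
    FALSE
  }
  repeat {
    repeat {   # stepwise descent to a local minimum
      moved <- FALSE
      cur <- c(best$p, best$q, best$P, best$Q)
      for (dv in deltas)
        if (try_move(cur + dv)) moved <- TRUE
      if (!moved) break
    }
    # mixed ARMA forms can trap the stepwise on a ridge between the AR-pure
    # and MA-pure representations of the same correlation structure; since
    # pure forms are the typical identification outcome, check them
    # explicitly (same total order, plus one) before accepting the minimum
    cur <- c(best$p, best$q, best$P, best$Q)
    escaped <- FALSE
    for (k in 0:min(max(max_p, max_q), cur[1] + cur[2] + 1L)) {
      if (try_move(c(k, 0L, cur[3], cur[4]))) escaped <- TRUE
      if (try_move(c(0L, k, cur[3], cur[4]))) escaped <- TRUE
    }
    if (s > 1L) for (k in 0:min(max(max_P, max_Q), cur[3] + cur[4] + 1L)) {
      if (try_move(c(best$p, best$q, k, 0L))) escaped <- TRUE
      if (try_move(c(best$p, best$q, 0L, k))) escaped <- TRUE
    }
    if (!escaped) break
  }

  structure(list(best = best$fit, order = best$fit$order,
                 criterion = criterion, criterion_value = best$crit,
                 trace = do.call(rbind, trace)),
            class = "sarima_search")
}

#' @export
print.sarima_search <- function(x, ...) {
  cat(sprintf("Stepwise SARIMA search (%s): selected %s, %s = %.2f (%d orders tried)\n",
              toupper(x$criterion), format(x$order), toupper(x$criterion),
              x$criterion_value, nrow(x$trace)))
  invisible(x)
}

#' Recommend differencing degrees
#'
#' Advisory heuristic mirroring the usual visual workflow: a seasonal
#' difference (`D = 1`) is recommended when the lag-`s` autocorrelation of
#' the linearly detrended series exceeds its white-noise significance band;
#' the regular degree `d` is then chosen by repeated unit-root testing
#' ([adf_test()]) on the (seasonally) differenced series, stopping at the
#' first `d` (0, 1 or 2) for which the unit root is rejected. The analyst's
#' judgement overrides this recommendation.
#'
#' @param series an `its_series` (or `ts`).
#' @param alpha significance level for the unit-root decisions.
#' @return list with `d`, `D` and a human-readable `rationale`.
#' @export
choose_differencing <- function(series, alpha = 0.05) {
  series <- as_its_series(series)
  s <- stats::frequency(series)
  n <- length(series)
  rationale <- character(0)

  D <- 0L
  if (s > 1L) {
    if (n < 2L * s + 10L) {
      warning(sprintf(
        "series too short (%d) to assess seasonality at period %d; assuming D = 0",
        n, s))
      rationale <- c(rationale, sprintf(
        "Series too short to assess seasonality at period %d; D = 0 assumed.", s))
    } else {
      # detrend by first-differencing (robust to stochastic as well as
      # linear trends), then look for a positive lag-s autocorrelation spike
      det <- diff(as.numeric(series))
      r <- as.numeric(stats::acf(det, lag.max = s, plot = FALSE)$acf)[s + 1L]
      band <- 1.96 / sqrt(length(det))
      if (r > band) {
        D <- 1L
        rationale <- c(rationale, sprintf(
          "Detrended (first-differenced) autocorrelation at lag %d is %.3f, above the band (+/- %.3f): seasonal difference D = 1 recommended.",
          s, r, band))
      } else rationale <- c(rationale, sprintf(
        "Detrended (first-differenced) autocorrelation at lag %d is %.3f, inside the band (+/- %.3f): no seasonal difference (D = 0).",
        s, r, band))
    }
  }

  # repeated unit-root testing (BIC lag choice keeps the test powered on
  # short series), with the classical variance-reduction check as an
  # over-differencing guard: if one more difference would inflate the
  # variance, the series is treated as stationary at the current degree
  work <- series
  if (D == 1L) work <- difference(work, lag = s)
  d <- 0L
  repeat {
    res <- tryCatch(adf_test(work, alpha = alpha, lag_criterion = "bic"),
                    error = function(e) NULL)
    if (is.null(res)) {
      rationale <- c(rationale,
                     "Unit-root test degenerate after differencing; stopping.")
      break
    }
    if (res$reject_unit_root) {
      rationale <- c(rationale, sprintf(
        "ADF on the d = %d series rejects a unit root (tau = %.2f, p = %.3f): stationary.",
        d, res$statistic, res$p_value))
      break
    }
    if (d >= 2L) {
      rationale <- c(rationale,
                     "Unit root still not rejected at d = 2; higher-order differencing is rarely justified, stopping at d = 2.")
      break
    }
    nxt <- difference(work, lag = 1L)
    if (stats::var(as.numeric(nxt)) >= stats::var(as.numeric(work))) {
      rationale <- c(rationale, sprintf(
        "ADF on the d = %d series cannot reject a unit root (tau = %.2f, p = %.3f), but a further difference would inflate the variance (over-differencing): stopping at d = %d.",
        d, res$statistic, res$p_value, d))
      break
    }
    rationale <- c(rationale, sprintf(
      "ADF on the d = %d series cannot reject a unit root (tau = %.2f, p = %.3f): differencing once more.",
      d, res$statistic, res$p_value))
    d <- d + 1L
    work <- nxt
  }

  list(d = d, D = D, rationale = paste(rationale, collapse = " "))
}

#' Search over candidate onset delays
#'
#' Refits a fixed model order with every intervention onset shifted by each
#' candidate delay in `0..window`, and returns the criterion-minimising
#' delay together with the full comparison table. Use this to resolve a
#' prespecified range of plausible lags between an intervention's nominal
#' date and its observable impact.
#'
#' @param series an `its_series`.
#' @param order an [arima_order()].
#' @param interventions list of [intervention()] specs (their own `delay`
#'   fields are kept and the candidate delay added on top).
#' @param window largest candidate delay (time units); candidates are
#'   `0..window`.
#' @param criterion `"aicc"`, `"aic"` or `"bic"`.
#' @return list of class `delay_search`: `best_delay`, `fits` (one per
#'   delay), and `table` (delay, converged, criterion; `window + 1` rows).
#' @export
delay_search <- function(series, order, interventions, window = 3L,
                         criterion = c("aicc", "aic", "bic")) {
  criterion <- match.arg(criterion)
  series <- as_its_series(series)
  window <- as.integer(window)
  if (window < 0L) stop("'window' must be >= 0", call. = FALSE)
  if (inherits(interventions, "intervention"))
    interventions <- list(interventions)
  onsets <- vapply(interventions, function(sp)
    onset_position(sp, series), 0L)
  post_len <- length(series) - min(onsets) + 1L
  if (window >= post_len)
    stop(sprintf(
      "delay window (%d) exceeds the post-intervention period (%d observations)",
      window, post_len), call. = FALSE)

  rows <- list(); fits <- list()
  for (k in 0:window) {
    shifted <- lapply(interventions, function(sp) {
      sp$delay <- sp$delay + k
      sp
    })
    fit <- tryCatch(sarima_fit(series, order, interventions = shifted),
                    error = function(e) NULL)
    fits[[k + 1L]] <- fit
    rows[[k + 1L]] <- data.frame(
      delay = k, converged = !is.null(fit),
      criterion = if (is.null(fit)) NA_real_ else fit[[criterion]])
  }
  tab <- do.call(rbind, rows)
  ok <- which(tab$converged)
  if (!length(ok)) stop("no delay candidate converged", call. = FALSE)
  best <- ok[which.min(tab$criterion[ok])]
  structure(list(best_delay = tab$delay[best], best_fit = fits[[best]],
                 fits = fits, table = tab, criterion = criterion),
            class = "delay_search")
}

#' @export
print.delay_search <- function(x, ...) {
  cat(sprintf("Onset delay search (%s): best delay = %d\n",
              toupper(x$criterion), x$best_delay))
  print(x$table, row.names = FALSE)
  invisible(x)
}
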