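#' Seasonal ARIMA model order
#'
#' The `(p, d, q) x (P, D, Q)_s` tuple naming the autoregressive order,
#' degree of differencing and moving-average order of the regular and
#' seasonal parts of a seasonal ARIMA model.
#'
#' @param p,d,q non-negative integers: regular AR order, differencing
#'   degree, MA order.
#' @param P,D,Q non-negative integers: seasonal counterparts.
#' @param s seasonal period (12 monthly, 4 quarterly, 1 non-seasonal).
#' @return an object of class `arima_order`.
#' @examples
#' arima_order(2, 1, 0, P = 0, D = 1, Q = 1, s = 12)
#' @export
arima_order <- function(p, d, q, P = 0L, D = 0L, Q = 0L, s = 1L) {
  v <- vapply(list(p, d, q, P, D, Q, s), as.integer, 0L)
  if (anyNA(v) || any(v < 0L))
    stop("all order components must be non-negative integers", call. = FALSE)
  names(v) <- c("p", "d", "q", "P", "D", "Q", "s")
  if (v["s"] < 1L) stop("seasonal period 's' must be >= 1", call. = FALSE)
  if (v["s"] == 1L && any(v[c("P", "D", "Q")] > 0L))
    stop("seasonal orders P, D, Q must be 0 when s = 1", call. = FALSE)
  if (v["d"] + v["D"] > 3L)
    stop("total differencing d + D greater than 3 is not supported (third-order differencing and above is rarely justified)",
         call. = FALSE)
  structure(as.list(v), class = "arima_order")
}

#' @export
format.arima_order <- function(x, ...) {
  if (x$s > 1L)
    sprintf("(%d,%d,%d)(%d,%d,%d)[%d]", x$p, x$d, x$q, x$P, x$D, x$Q, x$s)
  else sprintf("(%d,%d,%d)", x$p, x$d, x$q)
}

#' @export
print.arima_order <- function(x, ...) {
  cat("ARIMA order", format(x), "\n")
  invisible(x)
}

# ---- polynomial helpers ------------------------------------------------------

polymult <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <-
      out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

seasonal_lag_poly <- function(coefs, s, sign) {
  # (1 + sign * c_1 B^s + sign * c_2 B^2s + ...) as a dense coefficient vector
  out <- c(1, numeric(length(coefs) * s))
  for (j in seq_along(coefs)) out[j * s + 1L] <- sign * coefs[j]
  out
}

# Expand multiplicative SARMA polynomials to dense phi*/theta* lag vectors.
# Conventions: AR poly (1 - phi_1 B - ...), MA poly (1 + theta_1 B + ...).
expand_sarma <- function(phi, theta, Phi, Theta, s) {
  arp <- polymult(c(1, if (length(phi)) -phi else NULL),
                  seasonal_lag_poly(Phi, s, -1))
  map <- polymult(c(1, if (length(theta)) theta else NULL),
                  seasonal_lag_poly(Theta, s, +1))
  list(phi = if (length(arp) > 1L) -arp[-1L] else numeric(0),
       theta = if (length(map) > 1L) map[-1L] else numeric(0))
}

# ---- stationarity transform (partial-autocorrelation parameterisation) ------

pacf_to_ar <- function(pk) {
  phi <- numeric(0)
  for (k in seq_along(pk)) {
    phi <- if (k == 1L) pk[1L] else c(phi - pk[k] * rev(phi), pk[k])
  }
  phi
}

ar_to_pacf <- function(phi) {
  K <- length(phi)
  pk <- numeric(K)
  for (k in rev(seq_len(K))) {
    pk[k] <- phi[k]
    if (abs(pk[k]) >= 1) return(NULL)   # outside the stationary region
    if (k > 1L) {
      phi <- (phi[1:(k - 1L)] + pk[k] * rev(phi[1:(k - 1L)])) / (1 - pk[k]^2)
    }
  }
  pk
}

trans_to_coef <- function(z) pacf_to_ar(tanh(z))
coef_to_trans <- function(phi) {
  if (!length(phi)) return(numeric(0))
  pk <- ar_to_pacf(phi)
  if (is.null(pk)) return(NULL)
  atanh(pmax(pmin(pk, 1 - 1e-10), -1 + 1e-10))
}

ar_stationary <- function(phi, tol = 1e-8) {
  if (!length(phi)) return(TRUE)
  all(Mod(polyroot(c(1, -phi))) > 1 + tol)
}

# ---- exact Gaussian likelihood via the Kalman filter -------------------------

# Exact ARMA likelihood pieces from the compiled Kalman filter (Harvey
# state-space form, concentrated sigma^2). NULL signals an invalid
# parameter point (non-stationary AR part or degenerate filter).
arma_kalman <- function(w, phi, theta) {
  .kalman_arma(as.numeric(w), as.numeric(phi), as.numeric(theta), FALSE)
}

# Same filter, additionally returning the one-step-ahead state for
# forecasting.
arma_kalman_state <- function(w, phi, theta) {
  .kalman_arma(as.numeric(w), as.numeric(phi), as.numeric(theta), TRUE)
}

# Conditional sum of squares (starting values only).
arma_css <- function(w, phi, theta) {
  .css_arma(as.numeric(w), as.numeric(phi), as.numeric(theta))
}

# ---- parameter bookkeeping ---------------------------------------------------

# Parameter layout (natural scale): phi(p), theta(q), Phi(P), Theta(Q),
# beta (regression coefficients: intercept then one omega per intervention),
# delta (one per r>=1 intervention).
par_layout <- function(order, n_beta, n_delta) {
  list(phi = seq_len(order$p),
       theta = order$p + seq_len(order$q),
       Phi = order$p + order$q + seq_len(order$P),
       Theta = order$p + order$q + order$P + seq_len(order$Q),
       beta = order$p + order$q + order$P + order$Q + seq_len(n_beta),
       delta = order$p + order$q + order$P + order$Q + n_beta + seq_len(n_delta),
       n = order$p + order$q + order$P + order$Q + n_beta + n_delta)
}

split_par <- function(par, lay) {
  lapply(lay[c("phi", "theta", "Phi", "Theta", "beta", "delta")],
         function(ix) unname(par[ix]))
}
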