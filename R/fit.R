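#' Fit a seasonal ARIMA model with intervention regressors
#'
#' Estimates a `(p,d,q)(P,D,Q)_s` model for an observed series together
#' with step/pulse/ramp intervention impacts by exact Gaussian maximum
#' likelihood. The outcome and every intervention regressor are differenced
#' identically (`d` regular, `D` seasonal differences) — regression in
#' differences is equivalent to regression with ARIMA errors in levels, so
#' the impact coefficients stay interpretable in outcome units. The
#' likelihood of the differenced series is evaluated through a state-space
#' representation and the prediction-error decomposition (Kalman filter),
#' with conditional-sum-of-squares starting values refined by quasi-Newton
#' optimisation; for interventions with `r = 1` the decay rate `delta`
#' enters through the filtered regressor and is estimated jointly.
#'
#' Standard errors come from the inverse observed information (numerical
#' Hessian of the negative log-likelihood at the optimum); 95% confidence
#' intervals are Wald-style, `coefficient +/- 1.96 SE`.
#'
#' @param series an `its_series` (or `ts`).
#' @param order an [arima_order()]; its `s` must match the series frequency
#'   (a plain `c(p, d, q)` vector is also accepted).
#' @param interventions a single [intervention()] or a list of them; a
#'   combined impact (e.g. step + ramp at the same onset) is expressed as
#'   one list entry per shape.
#' @param include_constant include a mean/drift term for the differenced
#'   series. Default: `TRUE` when `d + D = 0` (the constant `c`), otherwise
#'   `FALSE` (a constant under differencing implies a deterministic
#'   polynomial trend).
#' @param method `"ml"` (exact maximum likelihood, default) or `"css"`
#'   (conditional sum of squares only, mainly for diagnostics).
#' @param optim_control passed to [stats::optim()] (`L-BFGS-B`); the
#'   default sets `factr = 1e4` (relative function tolerance near 1e-12)
#'   and `maxit = 500`.
#' @param restarts maximum number of perturbed restarts on optimizer
#'   failure (perturbations use an internal fixed-seed RNG stream and do
#'   not disturb the caller's random seed).
#' @return an object of class `sarima_fit`; see Details for components.
#' @examples
#' set.seed(1)
#' y <- its_series(arima.sim(list(ar = 0.5), 200) + 10, start = c(2000, 1),
#'                 frequency = 12)
#' fit <- sarima_fit(y, arima_order(1, 0, 0, s = 12))
#' coef(fit)
#' @export
sarima_fit <- function(series, order, interventions = list(),
                       include_constant = NULL,
                       method = c("ml", "css"),
                       optim_control = list(), restarts = 5L) {
  method <- match.arg(method)
  series <- as_its_series(series)
  s <- as.integer(stats::frequency(series))
  if (!inherits(order, "arima_order")) {
    order <- as.integer(order)
    order <- arima_order(order[1L], order[2L], order[3L],
                         P = if (length(order) >= 6L) order[4L] else 0L,
                         D = if (length(order) >= 6L) order[5L] else 0L,
                         Q = if (length(order) >= 6L) order[6L] else 0L,
                         s = s)
  }
  if (order$s != s)
    stop(sprintf("order has seasonal period %d but the series frequency is %d",
                 order$s, s), call. = FALSE)
  if (inherits(interventions, "intervention"))
    interventions <- list(interventions)
  if (!all(vapply(interventions, inherits, TRUE, "intervention")))
    stop("'interventions' must be intervention objects", call. = FALSE)
  if (is.null(include_constant)) include_constant <- (order$d + order$D == 0L)

  n <- length(series)
  d <- order$d; D <- order$D
  n_eff <- n - d - D * s
  diff_fun <- function(v) {
    if (d > 0L) for (i in seq_len(d)) v <- diff(v, lag = 1L)
    if (D > 0L) for (i in seq_len(D)) v <- diff(v, lag = s)
    v
  }
  if (n_eff < 3L)
    stop(sprintf("series too short: differencing d=%d, D=%d at s=%d leaves %d observations",
                 d, D, s, n_eff), call. = FALSE)

  # level-scale intervention inputs; unit-omega transfer applied per spec
  labs <- make_unique_labels(vapply(interventions, `[[`, "", "label"))
  ind_level <- lapply(interventions, intervention_indicator, timeline = series)
  is_dyn <- vapply(interventions, function(sp) sp$r >= 1L, TRUE)
  n_delta <- sum(is_dyn)

  beta_names <- c(if (include_constant) "intercept", labs)
  n_beta <- length(beta_names)
  lay <- par_layout(order, n_beta, n_delta)
  if (n_eff < lay$n + 2L)
    stop(sprintf("insufficient data: %d effective observations for %d free coefficients (need at least %d)",
                 n_eff, lay$n, lay$n + 2L), call. = FALSE)

  y_diff <- diff_fun(as.numeric(series))

  build_X <- function(delta) {
    cols <- vector("list", length(interventions))
    di <- 0L
    for (i in seq_along(interventions)) {
      v <- as.numeric(ind_level[[i]])
      if (is_dyn[i]) {
        di <- di + 1L
        v <- as.numeric(apply_transfer(v, omega = 1, delta = delta[di]))
      }
      cols[[i]] <- diff_fun(v)
    }
    args <- c(if (include_constant) list(rep(1, n_eff)), cols)
    X <- if (length(args)) do.call(cbind, args) else matrix(0, n_eff, 0L)
    colnames(X) <- beta_names
    X
  }

  negll <- function(par, transformed, use_css = FALSE) {
    pp <- split_par(par, lay)
    if (transformed) {
      phi <- trans_to_coef(pp$phi); theta <- trans_to_coef(pp$theta)
      Phi <- trans_to_coef(pp$Phi); Theta <- trans_to_coef(pp$Theta)
      delta <- tanh(pp$delta)
    } else {
      phi <- pp$phi; theta <- pp$theta; Phi <- pp$Phi; Theta <- pp$Theta
      delta <- pp$delta
      if (!ar_stationary(phi) || !ar_stationary(Phi) ||
          (length(delta) && any(abs(delta) >= 1))) return(1e10)
    }
    ex <- expand_sarma(phi, theta, Phi, Theta, s)
    X <- build_X(delta)
    w <- y_diff - if (ncol(X)) as.vector(X %*% pp$beta) else 0
    if (use_css) {
      val <- arma_css(w, ex$phi, ex$theta)
      if (is.null(val) || !is.finite(val)) return(1e10)
      return(val)
    }
    kf <- arma_kalman(w, ex$phi, ex$theta)
    if (is.null(kf) || !is.finite(kf$loglik)) return(1e10)
    -kf$loglik
  }

  # starting values: OLS betas at neutral deltas, ARMA from zero, CSS warm-up
  delta0 <- rep(0.3, n_delta)
  X0 <- build_X(delta0)
  beta0 <- if (ncol(X0)) {
    b <- tryCatch(stats::lm.fit(X0, y_diff)$coefficients,
                  error = function(e) rep(0, ncol(X0)))
    b[!is.finite(b)] <- 0
    unname(b)
  } else numeric(0)
  start <- numeric(lay$n)
  start[lay$beta] <- beta0
  start[lay$delta] <- atanh(delta0)

  # transformed ARMA/decay parameters are boxed away from the tanh
  # saturation plateau (tanh(6) = 0.99999); betas are unbounded
  lower <- rep(-Inf, lay$n); upper <- rep(Inf, lay$n)
  zidx <- c(lay$phi, lay$theta, lay$Phi, lay$Theta, lay$delta)
  lower[zidx] <- -6; upper[zidx] <- 6
  run_optim <- function(par0, fn) {
    if (!length(par0)) return(list(par = par0, value = fn(par0), convergence = 0L))
    scale <- rep(1, length(par0))
    scale[lay$beta] <- pmax(abs(par0[lay$beta]), 1)
    ctl <- utils::modifyList(list(factr = 1e4, maxit = 500L,
                                  parscale = scale), optim_control)
    stats::optim(pmin(pmax(par0, lower), upper), fn, method = "L-BFGS-B",
                 lower = lower, upper = upper, control = ctl)
  }

  css_fit <- tryCatch(
    run_optim(start, function(p) negll(p, transformed = TRUE, use_css = TRUE)),
    error = function(e) NULL)
  start_css <- if (!is.null(css_fit) && is.finite(css_fit$value) &&
                   css_fit$value < 1e9) css_fit$par else NULL

  target <- function(p) negll(p, transformed = TRUE,
                              use_css = (method == "css"))
  bad <- function(o) is.null(o) || !is.finite(o$value) || o$value >= 1e9 ||
    o$convergence != 0L

  # multi-start: mixed ARMA likelihoods can hold several local optima, so
  # the exact-ML refinement is run from both the CSS warm start and the
  # neutral start, keeping the better optimum
  starts <- list(start)
  if (!is.null(start_css) && any(abs(start_css - start) > 1e-8))
    starts <- c(list(start_css), starts)
  if (order$p > 0L && order$q > 0L) {
    # mixed models: AR/MA near-cancellation creates mirrored local optima;
    # probe both sign patterns of the ARMA block as additional starts
    for (sgn in c(0.6, -0.6)) {
      extra <- start
      extra[c(lay$phi, lay$Phi)] <- sgn
      extra[c(lay$theta, lay$Theta)] <- -sgn
      starts <- c(starts, list(extra))
    }
  }
  opt <- NULL
  for (p0 in starts) {
    cand <- tryCatch(run_optim(p0, target), error = function(e) NULL)
    if (!bad(cand) && (is.null(opt) || bad(opt) || cand$value < opt$value))
      opt <- cand
    else if (is.null(opt)) opt <- cand
  }
  tries <- 0L
  if (bad(opt) && lay$n > 0L) {
    perturb <- local_rng_stream(20240101L)
    base0 <- if (!is.null(start_css)) start_css else start
    while (bad(opt) && tries < restarts) {
      tries <- tries + 1L
      p0 <- base0 + perturb(lay$n) * 0.4
      cand <- tryCatch(run_optim(p0, target), error = function(e) NULL)
      if (!bad(cand) && (bad(opt) || cand$value < opt$value)) opt <- cand
    }
  }
  if (bad(opt) && !(is.finite(opt$value %||% Inf) && opt$value < 1e9))
    stop(sprintf(
      "SARIMA optimisation failed to converge for order %s after %d restarts (optim code %s, value %s)",
      format(order), tries,
      if (is.null(opt)) "NA" else opt$convergence,
      if (is.null(opt)) "NA" else format(opt$value)), call. = FALSE)

  # natural-scale coefficients
  pp <- split_par(opt$par, lay)
  coef_nat <- c(trans_to_coef(pp$phi), trans_to_coef(pp$theta),
                trans_to_coef(pp$Phi), trans_to_coef(pp$Theta),
                pp$beta, tanh(pp$delta))
  coef_names <- c(num_names("ar", order$p), num_names("ma", order$q),
                  num_names("sar", order$P), num_names("sma", order$Q),
                  beta_names,
                  if (n_delta) paste0("delta_", labs[is_dyn]))
  names(coef_nat) <- coef_names

  ppn <- split_par(coef_nat, lay)
  ex <- expand_sarma(ppn$phi, ppn$theta, ppn$Phi, ppn$Theta, s)
  Xhat <- build_X(ppn$delta)
  w <- y_diff - if (ncol(Xhat)) as.vector(Xhat %*% ppn$beta) else 0
  kf <- arma_kalman(w, ex$phi, ex$theta)
  if (is.null(kf))
    stop("likelihood evaluation failed at the reported optimum", call. = FALSE)
  if (length(ex$theta) && !ar_stationary(-ex$theta, tol = 1e-6))
    warning("MA polynomial is on the invertibility boundary; standard errors may be unreliable")

  loglik <- kf$loglik
  sigma2 <- kf$sigma2
  k_par <- lay$n + 1L   # all free coefficients plus sigma^2
  aic <- -2 * loglik + 2 * k_par
  bic <- -2 * loglik + k_par * log(n_eff)
  aicc <- if (n_eff - k_par - 1L > 0L)
    aic + 2 * k_par * (k_par + 1L) / (n_eff - k_par - 1L) else Inf

  # observed information in the natural parameter space
  vcov <- matrix(NA_real_, lay$n, lay$n,
                 dimnames = list(coef_names, coef_names))
  if (lay$n > 0L) {
    H <- tryCatch(
      stats::optimHess(coef_nat, function(p)
        negll(p, transformed = FALSE, use_css = (method == "css"))),
      error = function(e) NULL)
    if (!is.null(H)) {
      Vi <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(Vi) && all(is.finite(diag(Vi))) && all(diag(Vi) > 0))
        vcov <- structure(Vi, dimnames = list(coef_names, coef_names))
      else warning("observed information is singular or not positive definite; standard errors unavailable")
    } else warning("Hessian computation failed; standard errors unavailable")
  }

  dser <- series
  if (d > 0L) dser <- difference(dser, lag = 1L, times = d)
  if (D > 0L) dser <- difference(dser, lag = s, times = D)
  resid_ts <- its_series(kf$v, start = stats::start(dser), frequency = s,
                         label = "innovations")

  fitted_level <- as.numeric(series)
  fitted_level[(n - n_eff + 1L):n] <-
    as.numeric(series)[(n - n_eff + 1L):n] - kf$v

  structure(list(
    coef = coef_nat,
    se = sqrt(diag(vcov)),
    vcov = vcov,
    sigma2 = sigma2,
    loglik = loglik,
    aic = aic, aicc = aicc, bic = bic,
    k = k_par,
    order = order,
    interventions = interventions,
    intervention_labels = labs,
    include_constant = include_constant,
    method = method,
    series = series,
    residuals = resid_ts,
    fitted = its_series(fitted_level, start = stats::start(series),
                        frequency = s, label = "one-step predictions"),
    n_effective = n_eff,
    nobs = n,
    layout = lay,
    optim = list(value = opt$value, convergence = opt$convergence,
                 restarts_used = tries),
    call = match.call()
  ), class = "sarima_fit")
}

make_unique_labels <- function(labs) {
  if (!length(labs)) return(character(0))
  make.unique(labs, sep = "_")
}

num_names <- function(stem, k) if (k) paste0(stem, seq_len(k)) else character(0)

# deterministic perturbation stream that leaves the caller's RNG untouched
local_rng_stream <- function(seed) {
  state <- new.env()
  state$i <- 0L
  function(k) {
    state$i <- state$i + 1L
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", globalenv()))
              rm(".Random.seed", envir = globalenv()))
    set.seed(seed + state$i)
    stats::rnorm(k)
  }
}

# ---- methods -----------------------------------------------------------------

#' @export
coef.sarima_fit <- function(object, ...) object$coef

#' @export
vcov.sarima_fit <- function(object, ...) object$vcov

#' @export
logLik.sarima_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n_effective,
            class = "logLik")
}

#' @export
residuals.sarima_fit <- function(object, ...) object$residuals

#' @export
fitted.sarima_fit <- function(object, ...) object$fitted

#' @export
nobs.sarima_fit <- function(object, ...) object$n_effective

#' Wald 95% confidence intervals for fitted coefficients
#' @param object a `sarima_fit`.
#' @param parm coefficient names (default all).
#' @param level confidence level.
#' @param ... unused.
#' @return matrix with lower/upper columns.
#' @export
confint.sarima_fit <- function(object, parm = names(object$coef),
                               level = 0.95, ...) {
  z <- stats::qnorm((1 + level) / 2)
  est <- object$coef[parm]
  se <- object$se[parm]
  out <- cbind(lower = est - z * se, upper = est + z * se)
  rownames(out) <- parm
  out
}

#' @export
print.sarima_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Seasonal ARIMA %s fitted by %s to '%s' (n = %d, effective n = %d)\n",
              format(x$order), if (x$method == "ml") "exact ML" else "CSS",
              attr(x$series, "label"), x$nobs, x$n_effective))
  if (length(x$coef)) {
    tab <- cbind(estimate = x$coef, se = x$se,
                 lower95 = x$coef - 1.96 * x$se,
                 upper95 = x$coef + 1.96 * x$se)
    print(round(tab, digits))
  } else cat("  (no free coefficients)\n")
  cat(sprintf("sigma^2 = %.6g, log-likelihood = %.4f\n", x$sigma2, x$loglik))
  cat(sprintf("AIC = %.2f, AICc = %.2f, BIC = %.2f\n", x$aic, x$aicc, x$bic))
  invisible(x)
}

#' Serialise a fitted model summary
#'
#' @param fit a `sarima_fit`.
#' @param path optional file path; when given, JSON is written there.
#' @return the summary list, invisibly when writing to file.
#' @export
model_summary_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "sarima_fit"))
  ci <- if (length(fit$coef)) confint(fit) else
    matrix(numeric(0), 0, 2, dimnames = list(NULL, c("lower", "upper")))
  out <- list(
    order = unclass(fit$order),
    coefficients = as.list(fit$coef),
    standard_errors = as.list(fit$se),
    ci95 = list(lower = as.list(stats::setNames(ci[, 1], rownames(ci))),
                upper = as.list(stats::setNames(ci[, 2], rownames(ci)))),
    sigma2 = fit$sigma2,
    loglik = fit$loglik,
    aic = fit$aic, aicc = fit$aicc, bic = fit$bic,
    n = fit$nobs, n_effective = fit$n_effective,
    interventions = lapply(fit$interventions, unclass)
  )
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(out))
  }
  out
}

# ---- forecasting -------------------------------------------------------------

#' Forecast from a fitted SARIMA intervention model
#'
#' Minimum-MSE forecasts with 95% prediction intervals. Intervention
#' regressors are extended deterministically beyond the sample from their
#' specifications (set `zero_interventions = TRUE` for the counterfactual
#' regressor path of all-zero impacts). Point forecasts continue the
#' Kalman recursion on the differenced scale and are then integrated back
#' to levels; interval widths use the psi-weight (infinite MA)
#' representation of the full ARIMA operator, so they are non-decreasing in
#' the horizon.
#'
#' @param object a `sarima_fit`.
#' @param horizon number of periods ahead (>= 1).
#' @param level prediction-interval coverage (default 0.95).
#' @param zero_interventions zero out all intervention regressors in the
#'   future path (counterfactual forecasting).
#' @param ... unused.
#' @return a data frame of class `sarima_forecast` with columns `horizon`,
#'   `date`, `forecast`, `se`, `lower`, `upper`.
#' @export
predict.sarima_fit <- function(object, horizon = 12L, level = 0.95,
                               zero_interventions = FALSE, ...) {
  horizon <- as.integer(horizon)
  if (horizon < 1L) stop("'horizon' must be >= 1", call. = FALSE)
  fc <- sarima_path_forecast(object, horizon, zero_interventions)
  z <- stats::qnorm((1 + level) / 2)
  s <- stats::frequency(object$series)
  lastp <- stats::end(object$series)
  dates <- vapply(seq_len(horizon), function(j) {
    cyc <- lastp[2L] + j
    format_period(c(lastp[1L] + (cyc - 1L) %/% s, (cyc - 1L) %% s + 1L), s)
  }, "")
  out <- data.frame(horizon = seq_len(horizon), date = dates,
                    forecast = fc$mean, se = fc$se,
                    lower = fc$mean - z * fc$se,
                    upper = fc$mean + z * fc$se)
  class(out) <- c("sarima_forecast", "data.frame")
  out
}

# shared forecasting core: returns level-scale mean path and forecast SEs
sarima_path_forecast <- function(object, horizon, zero_interventions = FALSE,
                                 observed = NULL) {
  ord <- object$order
  s <- ord$s; d <- ord$d; D <- ord$D
  series <- if (is.null(observed)) object$series else observed
  n <- length(series)
  ppn <- split_par(object$coef, object$layout)
  ex <- expand_sarma(ppn$phi, ppn$theta, ppn$Phi, ppn$Theta, s)

  diff_fun <- function(v) {
    if (d > 0L) for (i in seq_len(d)) v <- diff(v, lag = 1L)
    if (D > 0L) for (i in seq_len(D)) v <- diff(v, lag = s)
    v
  }

  # extended regressor design on the differenced scale
  ext_len <- n + horizon
  ext_timeline <- its_series(numeric(ext_len), start = stats::start(series),
                             frequency = s)
  cols <- list()
  if (object$include_constant) cols <- c(cols, list(rep(1, ext_len - d - D * s)))
  di <- 0L
  deltas <- ppn$delta
  for (i in seq_along(object$interventions)) {
    sp <- object$interventions[[i]]
    v <- as.numeric(intervention_indicator(sp, ext_timeline))
    if (sp$r >= 1L) {
      di <- di + 1L
      v <- as.numeric(apply_transfer(v, omega = 1, delta = deltas[di]))
    }
    if (zero_interventions) v[] <- 0
    cols[[length(cols) + 1L]] <- diff_fun(v)
  }
  Xext <- if (length(cols)) do.call(cbind, cols) else
    matrix(0, ext_len - d - D * s, 0L)

  n_eff <- object$n_effective
  y_diff <- diff_fun(as.numeric(series))
  w <- y_diff - if (ncol(Xext)) as.vector(Xext[seq_len(n_eff), , drop = FALSE] %*% ppn$beta) else 0

  kf <- arma_kalman_state(w, ex$phi, ex$theta)
  if (is.null(kf)) stop("Kalman filtering failed during forecasting", call. = FALSE)

  # point forecasts of the ARMA part of the differenced series
  wf <- numeric(horizon)
  a <- kf$a
  for (j in seq_len(horizon)) {
    wf[j] <- a[1L]
    a <- as.vector(kf$T %*% a)
  }
  dfc <- wf + if (ncol(Xext))
    as.vector(Xext[n_eff + seq_len(horizon), , drop = FALSE] %*% ppn$beta) else 0

  # integrate the differencing operator back to the level scale
  diffpoly <- c(1)
  if (d > 0L) for (i in seq_len(d)) diffpoly <- polymult(diffpoly, c(1, -1))
  if (D > 0L) for (i in seq_len(D))
    diffpoly <- polymult(diffpoly, c(1, numeric(s - 1L), -1))
  cpoly <- diffpoly[-1L]   # y_t = dfc_t - sum_i cpoly_i * y_{t-i}
  buf <- as.numeric(series)
  mean_path <- numeric(horizon)
  for (j in seq_len(horizon)) {
    val <- dfc[j]
    if (length(cpoly))
      val <- val - sum(cpoly * buf[length(buf) - seq_along(cpoly) + 1L])
    buf <- c(buf, val)
    mean_path[j] <- val
  }

  # psi weights of the full (integrated) operator for forecast variances
  a_full <- polymult(c(1, if (length(ex$phi)) -ex$phi else NULL), diffpoly)
  arw <- -a_full[-1L]
  psi <- numeric(horizon)
  psi0 <- 1
  if (horizon > 1L) {
    th <- c(ex$theta, numeric(horizon))
    for (j in seq_len(horizon - 1L)) {
      acc <- th[j]
      if (length(arw)) {
        im <- seq_len(min(j, length(arw)))
        # psi_{j-i}, with psi_0 = 1 held implicitly
        acc <- acc + sum(arw[im] * vapply(im, function(i)
          if (j - i == 0L) 1 else psi[j - i], 0))
      }
      psi[j] <- acc
    }
  }
  cums <- cumsum(c(1, psi[seq_len(max(horizon - 1L, 0L))]^2))
  se <- sqrt(object$sigma2 * cums[seq_len(horizon)])
  list(mean = mean_path, se = se)
}
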