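#' Counterfactual series: model-implied outcome absent the intervention
#'
#' In the default (regression-adjusted) mode the counterfactual at each
#' time point is the model's one-step prediction minus the estimated
#' intervention contribution, i.e. the prediction with every intervention
#' regressor set to zero over the whole series; before the onset it equals
#' the fitted values exactly. The `"dynamic"` mode instead re-forecasts the
#' series from the last pre-intervention observation with a zero
#' intervention path — a sensitivity analysis in which post-onset
#' observations do not inform the counterfactual.
#'
#' @param model a `sarima_fit` with at least one intervention.
#' @param mode `"regression"` (default) or `"dynamic"`.
#' @return an `its_series` on the observed timeline.
#' @export
counterfactual <- function(model, mode = c("regression", "dynamic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "sarima_fit"))
  if (!length(model$interventions))
    stop("model was fitted without interventions; no counterfactual is defined",
         call. = FALSE)
  series <- model$series
  n <- length(series)
  if (mode == "regression") {
    cf <- as.numeric(model$fitted) - impact_path(model)
  } else {
    onset <- min(vapply(model$interventions, function(sp)
      onset_position(sp, series), 0L))
    if (onset <= 1L || onset > n)
      stop("dynamic counterfactual requires an onset inside the series",
           call. = FALSE)
    pre <- its_series(as.numeric(series)[seq_len(onset - 1L)],
                      start = stats::start(series),
                      frequency = stats::frequency(series))
    fc <- sarima_path_forecast(model, horizon = n - onset + 1L,
                               zero_interventions = TRUE, observed = pre)
    cf <- c(as.numeric(model$fitted)[seq_len(onset - 1L)], fc$mean)
  }
  its_series(cf, start = stats::start(series),
             frequency = stats::frequency(series),
             label = "counterfactual (no intervention)")
}

# estimated level-scale impact contribution of all interventions
impact_path <- function(model) {
  series <- model$series
  ppn <- split_par(model$coef, model$layout)
  omega <- ppn$beta
  if (model$include_constant) omega <- omega[-1L]
  deltas <- ppn$delta
  out <- numeric(length(series))
  di <- 0L
  for (i in seq_along(model$interventions)) {
    sp <- model$interventions[[i]]
    ind <- as.numeric(intervention_indicator(sp, series))
    if (sp$r >= 1L) {
      di <- di + 1L
      out <- out + as.numeric(apply_transfer(ind, omega = omega[i],
                                             delta = deltas[di]))
    } else {
      out <- out + omega[i] * ind
    }
  }
  out
}

#' Intervention effect at a post-onset horizon
#'
#' Sums the closed-form transfer-function response of every intervention at
#' `k` time units after the (earliest) onset, using the estimated impact
#' coefficients; the 95% confidence interval is a delta-method linear
#' combination of the coefficient covariance (exact linear combination when
#' all impacts have `r = 0`). For a step + ramp pair this reproduces the
#' familiar arithmetic `step + (k + 1) * ramp`.
#'
#' @param model a `sarima_fit`.
#' @param k non-negative horizon (0 = the onset period itself).
#' @param level confidence level.
#' @return list with `estimate`, `se`, `lower`, `upper`, `horizon`, and
#'   `flagged` (`TRUE` when `k` runs past the observed study period, where
#'   findings should no longer be considered valid).
#' @export
effect_at <- function(model, k, level = 0.95) {
  stopifnot(inherits(model, "sarima_fit"))
  k <- as.integer(k)
  if (k < 0L) stop("'k' must be >= 0", call. = FALSE)
  if (!length(model$interventions))
    return(list(estimate = 0, se = 0, lower = 0, upper = 0, horizon = k,
                flagged = FALSE))
  series <- model$series
  onsets <- vapply(model$interventions, function(sp)
    onset_position(sp, series), 0L)
  base <- min(onsets)
  flagged <- (base + k) > length(series)
  if (flagged)
    warning("horizon runs past the study period; the extrapolated effect should be interpreted with caution")

  ppn <- split_par(model$coef, model$layout)
  omega <- ppn$beta
  if (model$include_constant) omega <- omega[-1L]
  deltas <- ppn$delta

  est <- 0
  grad <- stats::setNames(numeric(length(model$coef)), names(model$coef))
  di <- 0L
  for (i in seq_along(model$interventions)) {
    sp <- model$interventions[[i]]
    ki <- k - (onsets[i] - base)   # horizon relative to this spec's onset
    lab <- model$intervention_labels[i]
    if (sp$r >= 1L) di <- di + 1L
    if (ki < 0L) next
    if (sp$r == 0L) {
      unit <- theoretical_response(sp$shape, omega0 = 1, k = ki, r = 0L)
      est <- est + omega[i] * unit
      grad[lab] <- grad[lab] + unit
    } else {
      dl <- deltas[di]
      unit <- theoretical_response(sp$shape, omega0 = 1, delta1 = dl,
                                   k = ki, r = 1L)
      est <- est + omega[i] * unit
      grad[lab] <- grad[lab] + unit
      dresp <- switch(sp$shape,
        pulse = if (ki == 0L) 0 else ki * dl^(ki - 1L),
        step = (-(ki + 1) * dl^ki * (1 - dl) + (1 - dl^(ki + 1))) / (1 - dl)^2,
        stop("unsupported r = 1 shape", call. = FALSE))
      grad[paste0("delta_", lab)] <- grad[paste0("delta_", lab)] +
        omega[i] * dresp
    }
  }
  se <- if (all(is.finite(model$vcov)))
    sqrt(max(0, as.numeric(t(grad) %*% model$vcov %*% grad))) else NA_real_
  z <- stats::qnorm((1 + level) / 2)
  list(estimate = est, se = se,
       lower = est - z * se, upper = est + z * se,
       horizon = k, flagged = flagged)
}

#' Pointwise and cumulative intervention effects with confidence intervals
#'
#' Evaluates [effect_at()] over a range of post-onset horizons and attaches
#' the observed and counterfactual trajectories, giving the plot-ready
#' summary of the intervention impact over the study period.
#'
#' @param model a `sarima_fit` with interventions.
#' @param horizons integer vector of post-onset horizons; defaults to every
#'   observed post-onset period.
#' @param level confidence level.
#' @param mode counterfactual mode, see [counterfactual()].
#' @return a data frame of class `its_effect_summary` with columns
#'   `horizon`, `date`, `effect`, `se`, `lower`, `upper`, `cumulative`;
#'   attributes `observed` and `counterfactual` hold the two trajectories.
#' @export
effect_summary <- function(model, horizons = NULL, level = 0.95,
                           mode = c("regression", "dynamic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "sarima_fit"))
  if (!length(model$interventions))
    stop("model was fitted without interventions", call. = FALSE)
  series <- model$series
  base <- min(vapply(model$interventions, function(sp)
    onset_position(sp, series), 0L))
  if (is.null(horizons)) horizons <- 0:(length(series) - base)
  labs <- period_labels(series)
  rows <- lapply(horizons, function(k) {
    e <- suppressWarnings(effect_at(model, k, level = level))
    data.frame(horizon = k,
               date = if (base + k <= length(series)) labs[base + k] else NA,
               effect = e$estimate, se = e$se, lower = e$lower,
               upper = e$upper)
  })
  out <- do.call(rbind, rows)
  out$cumulative <- cumsum(out$effect)
  attr(out, "observed") <- series
  attr(out, "counterfactual") <- counterfactual(model, mode = mode)
  class(out) <- c("its_effect_summary", "data.frame")
  out
}

#' @export
print.its_effect_summary <- function(x, digits = 2, ...) {
  cat("Intervention effect summary (outcome units)\n")
  df <- as.data.frame(x)
  df[] <- lapply(df, function(col) if (is.numeric(col)) round(col, digits)
                 else col)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an effect summary (and trajectories) to CSV
#'
#' `write_effect_csv()` writes the horizon-by-horizon effect table;
#' `write_counterfactual_csv()` writes the observed vs counterfactual
#' trajectories (the data behind an observed/predicted figure).
#'
#' @param x an `its_effect_summary`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_effect_csv <- function(x, path) {
  stopifnot(inherits(x, "its_effect_summary"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_effect_csv
#' @export
write_counterfactual_csv <- function(x, path) {
  stopifnot(inherits(x, "its_effect_summary"))
  obs <- attr(x, "observed"); cf <- attr(x, "counterfactual")
  utils::write.csv(data.frame(date = period_labels(obs),
                              observed = as.numeric(obs),
                              counterfactual = as.numeric(cf)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Serialise an effect summary to JSON
#' @param x an `its_effect_summary`.
#' @param path optional output file.
#' @return list form (invisibly when writing).
#' @export
effect_summary_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "its_effect_summary"))
  out <- list(effects = as.data.frame(x),
              observed = as.numeric(attr(x, "observed")),
              counterfactual = as.numeric(attr(x, "counterfactual")),
              dates = period_labels(attr(x, "observed")))
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(out))
  }
  out
}
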