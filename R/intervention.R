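#' Specify an intervention impact
#'
#' Describes one hypothesised impact of an intervention on the outcome
#' series: its shape (sustained step change, one-period pulse, or change in
#' slope / ramp), the calendar onset `T0`, an optional delay in whole time
#' units, and the orders `(h, r)` of the rational transfer function
#' `omega(B) / delta(B)` linking the input to the outcome. `h = 0` with
#' `r = 0` gives the plain step/pulse/ramp regressor; `r = 1` adds a
#' geometric decay (pulse) or gradual approach to a new level (step) with
#' rate `delta_1`.
#'
#' @param shape `"step"`, `"pulse"` or `"ramp"`.
#' @param onset calendar period of the intervention (`"YYYY-MM"`,
#'   `"YYYY-Qn"` or `c(year, cycle)`).
#' @param delay non-negative integer delay, in time units, added to the
#'   onset before the input takes effect.
#' @param h numerator order of the transfer function (only 0 is fully
#'   supported; larger values are accepted but flagged experimental).
#' @param r denominator order (0 or 1 fully supported).
#' @param label name used for the coefficient; defaults to the shape.
#' @return an object of class `intervention`.
#' @examples
#' intervention("step", onset = "2014-01")
#' intervention("pulse", onset = "2014-01", r = 1)
#' @export
intervention <- function(shape = c("step", "pulse", "ramp"), onset,
                         delay = 0L, h = 0L, r = 0L, label = NULL) {
  shape <- match.arg(shape)
  delay <- as.integer(delay); h <- as.integer(h); r <- as.integer(r)
  if (delay < 0L) stop("'delay' must be a non-negative integer", call. = FALSE)
  if (h < 0L || r < 0L)
    stop("transfer-function orders 'h' and 'r' must be non-negative",
         call. = FALSE)
  if (h > 0L)
    warning("h > 0 numerator lags are experimental; only h = 0 is fully supported")
  if (r > 1L)
    warning("r > 1 decay structures are experimental; only r in {0, 1} is fully supported")
  structure(list(shape = shape, onset = onset, delay = delay, h = h, r = r,
                 label = if (is.null(label)) shape else as.character(label)),
            class = "intervention")
}

#' @export
print.intervention <- function(x, ...) {
  on <- if (is.character(x$onset)) x$onset else
    paste(x$onset, collapse = "-")
  cat(sprintf("intervention '%s': %s at %s%s (h = %d, r = %d)\n",
              x$label, x$shape, on,
              if (x$delay > 0) sprintf(" + %d periods delay", x$delay) else "",
              x$h, x$r))
  invisible(x)
}

# Resolve an intervention's effective onset to a 1-based position on a
# timeline; positions past the end yield an inert (all-zero) input.
onset_position <- function(spec, timeline) {
  period_index(timeline, spec$onset) + spec$delay
}

#' Step, pulse and ramp indicator series
#'
#' The three canonical intervention inputs on the timeline of an observed
#' series: the step `S_t` is 0 before the onset `T0` and 1 from `T0` on; the
#' pulse `P_t` is 1 only at `T0`; the ramp `R_t` is 0 before `T0` and
#' `t - T0 + 1` from `T0` on (so it equals 1 at the onset itself).
#'
#' @param T0 calendar onset period (string or `c(year, cycle)`), or an
#'   `intervention` object (whose onset + delay are used).
#' @param timeline an `its_series` (or `ts`) supplying the calendar index.
#' @return an `its_series` of indicator values on the same timeline.
#' @examples
#' y <- its_series(rnorm(8), start = c(2020, 1), frequency = 12)
#' as.numeric(step_indicator("2020-05", y))
#' @export
step_indicator <- function(T0, timeline) {
  pos <- indicator_pos(T0, timeline)
  n <- length(timeline)
  v <- numeric(n)
  if (pos <= n) v[max(1L, pos):n] <- 1
  indicator_series(v, timeline, "step")
}

#' @rdname step_indicator
#' @export
pulse_indicator <- function(T0, timeline) {
  pos <- indicator_pos(T0, timeline)
  n <- length(timeline)
  v <- numeric(n)
  if (pos >= 1L && pos <= n) v[pos] <- 1
  indicator_series(v, timeline, "pulse")
}

#' @rdname step_indicator
#' @export
ramp_indicator <- function(T0, timeline) {
  pos <- indicator_pos(T0, timeline)
  n <- length(timeline)
  v <- pmax(seq_len(n) - pos + 1L, 0)
  indicator_series(v, timeline, "ramp")
}

indicator_pos <- function(T0, timeline) {
  if (length(timeline) < 1L) stop("empty timeline", call. = FALSE)
  pos <- if (inherits(T0, "intervention")) onset_position(T0, timeline)
  else period_index(timeline, T0)
  if (pos > length(timeline))
    warning("intervention onset falls after the end of the series; indicator is all zero")
  pos
}

indicator_series <- function(v, timeline, lab) {
  its_series(v, start = stats::start(timeline),
             frequency = stats::frequency(timeline), label = lab)
}

#' Build the indicator input for an intervention spec on a timeline
#' @param spec an `intervention`.
#' @param timeline an `its_series` (or `ts`).
#' @return an `its_series` indicator (delay applied).
#' @export
intervention_indicator <- function(spec, timeline) {
  stopifnot(inherits(spec, "intervention"))
  switch(spec$shape,
         step = step_indicator(spec, timeline),
         pulse = pulse_indicator(spec, timeline),
         ramp = ramp_indicator(spec, timeline))
}

#' Apply a rational transfer function to an input series
#'
#' Filters an intervention input `X_t` through
#' `omega(B) / delta(B) = (omega_0 + omega_1 B + ...) / (1 - delta_1 B - ...)`
#' by the recursion `y_t = sum_j delta_j y_{t-j} + sum_i omega_i x_{t-i}`
#' with zero initial conditions (no impact before the input turns on).
#'
#' @param x input `its_series` (or numeric vector).
#' @param omega numerator coefficients `omega_0..omega_h`, in outcome units.
#' @param delta denominator coefficients `delta_1..delta_r` (dimensionless);
#'   for `r = 1` stability requires `|delta_1| < 1`.
#' @return the filtered series, same class and timeline as `x`.
#' @examples
#' p <- its_series(c(0, 0, 1, 0, 0, 0), start = c(2020, 1), frequency = 12)
#' as.numeric(apply_transfer(p, omega = 10, delta = 0.5))
#' @export
apply_transfer <- function(x, omega, delta = numeric(0)) {
  if (length(omega) < 1L) stop("'omega' must have at least omega_0", call. = FALSE)
  if (length(delta) > 0L) {
    roots <- polyroot(c(1, -delta))
    if (any(Mod(roots) <= 1 + 1e-8))
      stop("unstable transfer function: delta polynomial root on or inside the unit circle",
           call. = FALSE)
  }
  v <- as.numeric(x)
  pad <- length(omega) - 1L   # zero-pad so the convolution start uses zero ICs
  num <- as.numeric(stats::filter(c(numeric(pad), v), omega,
                                  method = "convolution", sides = 1))
  if (pad > 0L) num <- num[-seq_len(pad)]
  out <- if (length(delta) > 0L)
    as.numeric(stats::filter(num, delta, method = "recursive")) else num
  if (inherits(x, "ts") || inherits(x, "its_series"))
    indicator_series(out, x, attr(x, "label") %||% "") else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Closed-form transfer-function response at a post-intervention horizon
#'
#' The textbook responses of the supported (shape, h, r) combinations at
#' `k = 0, 1, 2, ...` time units after the intervention onset:
#' \describe{
#'   \item{step, r = 0}{`omega_0` at every horizon (sustained level shift).}
#'   \item{step, r = 1}{`omega_0 (1 + delta_1 + ... + delta_1^k)`, rising
#'     towards the asymptote `omega_0 / (1 - delta_1)`.}
#'   \item{pulse, r = 0}{`omega_0` at `k = 0`, then 0.}
#'   \item{pulse, r = 1}{`omega_0 delta_1^k` (geometric decay).}
#'   \item{ramp, r = 0}{`(k + 1) omega_0` (change in slope).}
#' }
#'
#' @param shape `"step"`, `"pulse"` or `"ramp"`.
#' @param omega0 initial impact `omega_0`, in outcome units.
#' @param delta1 decay rate `delta_1` (required when `r = 1`).
#' @param k non-negative horizon(s), in time units since onset.
#' @param r denominator order (0 or 1).
#' @return numeric vector of responses, one per element of `k`.
#' @export
theoretical_response <- function(shape = c("step", "pulse", "ramp"),
                                 omega0, delta1 = NULL, k, r = 0L) {
  shape <- match.arg(shape)
  r <- as.integer(r)
  if (any(k < 0)) stop("'k' must be non-negative", call. = FALSE)
  if (r == 1L) {
    if (is.null(delta1)) stop("'delta1' required when r = 1", call. = FALSE)
    if (abs(delta1) >= 1)
      stop("unstable transfer function: |delta1| must be < 1", call. = FALSE)
  }
  if (r == 0L) {
    switch(shape,
           step = rep(omega0, length(k)),
           pulse = ifelse(k == 0, omega0, 0),
           ramp = (k + 1) * omega0)
  } else if (r == 1L) {
    switch(shape,
           step = omega0 * (1 - delta1^(k + 1)) / (1 - delta1),
           pulse = omega0 * delta1^k,
           ramp = stop("unsupported combination: ramp with r = 1 has no tabulated closed form",
                       call. = FALSE))
  } else {
    stop(sprintf("unsupported transfer order r = %d (supported: 0, 1)", r),
         call. = FALSE)
  }
}

#' Read intervention specifications from a YAML or JSON config file
#'
#' The file holds a list of intervention entries, each with fields `shape`,
#' `onset` and optionally `delay`, `h`, `r`, `label`, e.g.
#' ```yaml
#' interventions:
#'   - {shape: step, onset: 2014-01}
#'   - {shape: ramp, onset: 2014-01}
#' ```
#' A top-level list without the `interventions` key is also accepted.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return list of `intervention` objects.
#' @export
read_intervention_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  entries <- cfg$interventions %||% cfg
  if (!is.list(entries) || length(entries) == 0L)
    stop(sprintf("no intervention entries found in %s", path), call. = FALSE)
  lapply(entries, function(e) {
    if (is.null(e$shape) || is.null(e$onset))
      stop("each intervention entry needs 'shape' and 'onset'", call. = FALSE)
    intervention(shape = e$shape, onset = e$onset,
                 delay = e$delay %||% 0L, h = e$h %||% 0L, r = e$r %||% 0L,
                 label = e$label)
  })
}
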