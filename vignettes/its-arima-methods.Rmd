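---
title: "Evaluating interventions with seasonal ARIMA models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating interventions with seasonal ARIMA models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`itsarima` implements interrupted time series (ITS) analysis with seasonal
ARIMA models: a quasi-experimental design in which an outcome tracked
before and after an intervention is compared with the counterfactual
trajectory implied by its own pre-existing trend, seasonality and
autocorrelation. This vignette documents the model, the estimation
machinery, the numerical choices, and what the synthetic-data generator
does and does not emulate.

## The model

The observed outcome $Y_t$ (a count or rate at equally spaced calendar
periods, seasonal period $s$) is modelled as

$$Y_t = \mu + \sum_j \frac{\omega^{(j)}(B)}{\delta^{(j)}(B)} X^{(j)}_t + N_t,$$

where each $X^{(j)}_t$ is an intervention input — a step $S_t$
(0 before the onset $T_0$, 1 from $T_0$), a pulse $P_t$ (1 only at $T_0$)
or a ramp $R_t$ ($t - T_0 + 1$ from $T_0$) — filtered through a rational
transfer function in the backshift operator $B$, and the noise $N_t$
follows a multiplicative seasonal ARIMA process

$$\phi(B)\,\Phi(B^s)\,(1-B)^d\,(1-B^s)^D\, N_t = \theta(B)\,\Theta(B^s)\,\varepsilon_t,
\qquad \varepsilon_t \sim \mathcal N(0, \sigma^2).$$

The Gaussian-innovation assumption restricts the method to continuous
outcomes or counts large enough that a normal approximation is
reasonable; small Poisson-like counts need a different likelihood and are
out of scope.

For the supported transfer orders ($h = 0$; $r \in \{0, 1\}$) the impact
at $k$ periods after onset has a closed form
(`theoretical_response()`): a sustained shift $\omega_0$ (step, $r=0$), a
gradual approach to $\omega_0/(1-\delta_1)$ (step, $r=1$), a one-period
spike (pulse, $r=0$), geometric decay $\omega_0\delta_1^k$ (pulse, $r=1$),
or a slope change $(k+1)\,\omega_0$ (ramp, $r=0$). Higher orders are
accepted but flagged experimental; the filter `apply_transfer()` handles
them, but no closed form or delta-method interval is provided.

A combined impact — the worked example's step *and* ramp at the same
onset — is expressed as a list of separate intervention terms, each
contributing one regressor and one coefficient.

## Estimation

The outcome and every intervention regressor are differenced identically
($d$ regular and $D$ seasonal differences). Regression in differences is
equivalent to regression with ARIMA errors in levels, so the estimated
$\omega$'s remain interpretable in outcome units. On the differenced
scale the ARMA likelihood is evaluated exactly through the Harvey
state-space form and the prediction-error (Kalman filter) decomposition,
with $\sigma^2$ concentrated out; the initial state covariance solves the
stationary Lyapunov equation by a doubling iteration (tolerance
$10^{-12}$), and the filter is compiled (RcppArmadillo) since model
selection and the simulation-based tests fit thousands of models.

Numerical choices, in the order they matter:

* **Parameterisation.** AR and MA blocks (regular and seasonal) are
  optimised in the partial-autocorrelation transform
  ($z \mapsto \tanh z$, then the Durbin–Levinson map), which enforces
  stationarity/invertibility; decay rates $\delta_1$ use the same
  $\tanh$ map. Transformed coordinates are boxed to $[-6, 6]$
  ($\tanh 6 \approx 0.99999$) so the optimizer cannot stall on the
  saturation plateau.
* **Starting values and multi-start.** Regression coefficients start at
  OLS on the differenced design; ARMA terms start at zero and are warmed
  up by conditional-sum-of-squares minimisation. Exact ML is then run
  from both the CSS start and the neutral start — mixed ARMA likelihoods
  can hold mirrored local optima created by near-cancellation of AR and
  MA roots, so for models with both $p>0$ and $q>0$ two additional
  sign-pattern starts are probed, and the best optimum is kept.
* **Optimizer.** `L-BFGS-B` with `factr = 1e4` (relative tolerance near
  $10^{-12}$) and up to 500 iterations; on failure, up to five restarts
  from deterministically seeded perturbations (the caller's RNG stream is
  never touched). Non-convergence is an error carrying the optimizer
  diagnostics.
* **Uncertainty.** Standard errors come from the inverse observed
  information — a numerical Hessian of the negative log-likelihood taken
  in the *natural* coefficient space at the optimum; intervals are Wald,
  $\hat\beta \pm 1.96\,\mathrm{SE}$. A singular Hessian produces `NA`
  standard errors with a warning rather than an error.
* **Information criteria.** $k$ counts every free coefficient plus
  $\sigma^2$: $\mathrm{AIC} = -2\ell + 2k$,
  $\mathrm{BIC} = -2\ell + k\log n_\mathrm{eff}$,
  $\mathrm{AICc} = \mathrm{AIC} + 2k(k+1)/(n_\mathrm{eff}-k-1)$, with
  $n_\mathrm{eff} = n - d - Ds$.
* **Constant term.** Included by default only when $d + D = 0$ (a
  constant under differencing implies a deterministic polynomial trend
  the model family does not intend); user-overridable, in which case it
  is the mean of the differenced series (a drift).
* **Forecasting.** Point forecasts continue the Kalman recursion on the
  differenced scale and are integrated back through
  $(1-B)^d(1-B^s)^D$; forecast-error variances use the $\psi$-weight
  expansion of the full integrated operator, which makes interval width
  non-decreasing in the horizon.

## Differencing and order selection

`choose_differencing()` is advisory and mirrors the usual workflow.
Seasonal need ($D$): the lag-$s$ autocorrelation of the *first-differenced*
series is compared against the $1.96/\sqrt n$ band — first-differencing is
used as the detrending step because it also removes stochastic trends,
which otherwise dilute the seasonal spike on short series; only a positive
spike argues for $D = 1$. Regular need ($d$): repeated augmented
Dickey–Fuller testing (constant term; lag order chosen by BIC here, since
on 30–40 observations AIC-selected lag orders drain the test's power),
stopping at rejection, at $d = 2$, or when one further difference would
*increase* the sample variance — the classical over-differencing signal.
The ADF p-values use the MacKinnon response-surface approximation; a
constant-plus-trend variant is selectable.

`auto_sarima()` is a stepwise criterion search under the conventional
caps ($p, q \le 5$, $P, Q \le 2$, user-modifiable). Seeds are the cross
product of regular $\{(0,0), (1,0), (0,1), (2,2)\}$ and seasonal
$\{(0,0), (1,0), (0,1), (1,1)\}$ starting orders; moves change one of
$p, q, P, Q$ by $\pm 1$ or jointly shift $(p, q)$ or $(P, Q)$ by
$(\pm1, \pm1)$. When the stepwise descent stalls, the pure-AR and pure-MA
representations of comparable total order (and their seasonal analogues)
are evaluated explicitly before accepting the minimum: mixed ARMA forms
sit on a ridge between the AR-heavy and MA-heavy descriptions of the same
correlation structure, and the pure forms are the typical identification
outcome. Ties break towards parsimony (fewer parameters, then lower $q$,
then lower $p$). The search is deterministic given data and settings, the
full trace is returned, and the selected model's criterion value is the
minimum over everything evaluated.

The default criterion is AICc (small-sample correction of AIC); AIC and
BIC are selectable. For *order-recovery* questions — does the search find
the generating order? — BIC is the right tool (it is the consistent
criterion), and the package's order-recovery tests use it; AICc remains
the default because ITS practice cares more about adequate fit than about
recovering a "true" order.

`delay_search()` refits a fixed order with every onset delay in a
prespecified window `0..K` and reports the criterion-minimising delay
with the full comparison table — the recommended way to handle impacts
suspected to lag the nominal intervention date.

## Diagnostics

`ljung_box()` computes
$Q = n(n+2)\sum_{k=1}^{L} r_k^2/(n-k)$ against $\chi^2_{L - \mathrm{fitdf}}$.
`fitdf` counts only the ARMA terms ($p+q+P+Q$), not the constant or
$\sigma^2$ — the dominant convention, stated here because it changes the
degrees of freedom and hence the p-value. The default $L$ is
$\min(24, n_\mathrm{eff}/2)$, matching the common practice of two dozen
lags on a few years of monthly data. `residual_report()` adds the
residual ACF with its band, a Jarque–Bera normality check, and a
pass/fail verdict: *pass* when Ljung–Box does not reject white noise at
$\alpha = 0.05$.

## Counterfactual and effects

The counterfactual is the regression-adjusted prediction: the model's
one-step predictions minus the estimated intervention contribution
(equivalently, the prediction with every intervention regressor set to
zero). Before the onset it equals the fitted values exactly. This matches
the arithmetic by which step and ramp coefficients are added up into
"fewer events than predicted" statements: the effect at horizon $k$ is the
sum of each intervention's closed-form response, so a step $\hat\omega_s$
plus ramp $\hat\omega_r$ gives $\hat\omega_s + (k+1)\hat\omega_r$.
A dynamic mode (`counterfactual(..., mode = "dynamic")`) instead
re-forecasts from the last pre-onset observation with a zero intervention
path, as a sensitivity analysis; it uses no post-onset information.
Confidence intervals for effects are delta-method linear combinations of
the coefficient covariance (exact for $r = 0$ impacts). Horizons past the
end of the observed series are computed but flagged, since ITS findings
should not be extrapolated beyond the study period. On a log-transformed
outcome the effects are multiplicative and the summaries label them as
percent changes of the original scale.

## The synthetic-data generator

`make_sarima_dataset()` builds `series = deterministic baseline +
transfer-function impact signal + ARIMA noise` with a full truth record,
so every stage of the pipeline is testable without external data.
`quetiapine_fixture()` is the package's stand-in for a 48-month monthly
dispensing series with a policy intervention at month 37 (January of the
final year). Its default conditions, fixed once:

* baseline 28,000 dispensings rising 150/month; a fixed seasonal profile
  peaking near +4,400 in December with a trough near −2,700 in January —
  the end-of-calendar-year stockpiling ("Safety Net") pattern of
  subsidised-medicine claims;
* injected impacts: step −3,285 and ramp −1,397 dispensings at 2014-01
  (both $h = 0$, $r = 0$), the effect sizes reported for the policy this
  fixture emulates;
* noise: ARIMA$(2,1,0)(0,1,1)_{12}$ with $\phi = (-0.45, -0.35)$,
  $\Theta = -0.55$ and innovation SD 633 — the innovation scale is set so
  the step estimate's standard error (about 600 dispensings on this
  design) matches the precision of the published analysis, i.e. the
  signal-to-noise ratio is comparable to the real study rather than
  trivially favourable;
* default seed 2014.

What the fixture does *not* emulate: sampling variability in the seasonal
profile (the deterministic profile plus seasonal differencing implies a
seasonal MA component rather than evolving seasonality), policy
anticipation effects, outliers, and any non-Gaussian count structure.
Consequently, passing tests show that the pipeline recovers effects and
uncertainty correctly *under the model's own assumptions* — they cannot
show robustness to the ways real dispensing data violate those
assumptions. One further caveat is intrinsic to the sample size: on
35 effective observations the information criteria frequently prefer a
more parsimonious ARMA description than the generating order (the
generating order is not even the in-sample criterion optimum on many
realizations), so exact reproduction of a published order selection on a
synthetic realization is a coin-toss property, not a correctness
criterion for the search; the search's own contract — returning the
criterion minimum of everything it evaluates, deterministically — is what
the tests assert.

## Problem sizes used in the checks

The test-suite and acceptance-script simulation sizes are chosen to make
binomial noise small relative to the asserted bands while keeping a full
run in a few minutes on one core: 200 replicates at $n = 300$ for AR(1)
interval coverage (a 93–97% band), 50 synthetic ITS datasets at $n = 120$
for step-recovery coverage, 500 replicates at $n = 1000$ for Ljung–Box
size, 20 simulated datasets at $n = 200$ (orders up to
$(2,1,1)(1,1,1)_{12}$) for agreement with an independent ARIMA
implementation at $10^{-3}$ relative tolerance, and order-recovery runs
of 8–12 replicates at $n = 300$–800.

## Known limitations

* Gaussian likelihood only; no GLM-style count models.
* Transfer functions beyond $h = 0$, $r \le 1$ are filtered but not
  summarised; no cross-correlation-based delay identification.
* One seasonal polynomial pair (single seasonal period).
* No missing data, no irregular spacing: series are validated as
  complete and equally spaced at construction.
* The control-series design is supported by running the pipeline twice
  (once per series) and comparing narratively; no joint model is fitted.
* Wald intervals rely on the asymptotic normality of ML estimates; on
  very short series (a few dozen points) they can be optimistic,
  particularly for the seasonal MA coefficient.
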