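# itsarima

Interrupted time series (ITS) analysis with seasonal ARIMA intervention
models, for epidemiologists and health-services researchers evaluating
large-scale interventions — a new prescribing restriction, a co-payment
change, a media event — against a monthly or quarterly outcome series such
as dispensing claims, admissions or consultation counts.

Segmented regression, the most common ITS method, struggles when the
series carries strong autocorrelation and seasonality. `itsarima`
implements the ARIMA alternative end to end: the outcome
*Y<sub>t</sub>* is modelled as a seasonal ARIMA process
(*p*, *d*, *q*) × (*P*, *D*, *Q*)<sub>*s*</sub> plus intervention inputs
*X<sub>t</sub>* (step *S<sub>t</sub>*, pulse *P<sub>t</sub>*, ramp
*R<sub>t</sub>*) passed through a rational transfer function

&nbsp;&nbsp;&nbsp;&nbsp;*Y<sub>t</sub>* = *μ* +
[*ω*(B) / *δ*(B)] *X<sub>t</sub>* + *N<sub>t</sub>*,&nbsp;&nbsp;
*φ*(B) *Φ*(B<sup>s</sup>) (1−B)<sup>d</sup> (1−B<sup>s</sup>)<sup>D</sup>
*N<sub>t</sub>* = *θ*(B) *Θ*(B<sup>s</sup>) *ε<sub>t</sub>*,

where B is the backshift operator, *ω*<sub>0</sub> the initial impact in
outcome units and *δ*<sub>1</sub> a decay rate. Estimation is exact
Gaussian maximum likelihood via a state-space (Kalman filter)
prediction-error decomposition, with intervention regressors differenced
identically to the outcome so that impact coefficients stay interpretable
on the original scale.

What the package covers:

- **Series handling** — calendar-aware monthly/quarterly containers
  (`its_series`, `read_series_csv`), differencing, log transform,
  ACF/PACF correlograms (`correlogram`), augmented Dickey–Fuller
  unit-root test (`adf_test`), and a differencing recommendation
  (`choose_differencing`).
- **Interventions** — `intervention()` specs with step/pulse/ramp shapes,
  onset dates, delays and transfer orders (*h*, *r*); indicator builders;
  `apply_transfer()` and the closed-form `theoretical_response()`.
- **Estimation** — `sarima_fit()` (exact ML, joint estimation of decay
  rates, Wald intervals), `predict()` forecasts with prediction
  intervals, `simulate_sarima()`.
- **Model selection** — `auto_sarima()`, a stepwise information-criterion
  search under the usual caps (p, q ≤ 5; P, Q ≤ 2), and `delay_search()`
  over candidate onset delays.
- **Diagnostics** — `ljung_box()`, `jarque_bera()`, `residual_report()`
  with a white-noise verdict.
- **Effects** — `counterfactual()` (prediction with interventions zeroed),
  `effect_at()`, `effect_summary()` with delta-method confidence
  intervals, and CSV/JSON exports.
- **Synthetic data** — `make_sarima_dataset()` and
  `quetiapine_fixture()`, a fully synthetic 48-month dispensing-like
  series (rising trend, December-peak/January-trough "Safety Net"
  seasonality, negative step + ramp at month 37) with a recorded truth.
- **CLI** — `its_cli()` / `exec/itsarima` with `simulate`, `diagnose`,
  `auto`, `fit`, `effects` and `report` subcommands.

## Worked example

A policy restricting prescription refills is expected to cause an
immediate drop (step) plus a progressive decline (ramp) in monthly
dispensings from January 2014. On the bundled synthetic series:

```r
library(itsarima)

y <- read_series_csv(system.file("extdata", "quetiapine_synthetic.csv",
                                 package = "itsarima"))
specs <- list(intervention("step", onset = "2014-01"),
              intervention("ramp", onset = "2014-01"))

choose_differencing(y)[c("d", "D")]   # d = 1, D = 1

fit <- sarima_fit(y, arima_order(2, 1, 0, P = 0, D = 1, Q = 1, s = 12),
                  interventions = specs)
fit
#> Seasonal ARIMA (2,1,0)(0,1,1)[12] fitted by exact ML ... (n = 48, effective n = 35)
#>        estimate       se    lower95    upper95
#> ar1     -0.5394   0.1669    -0.8664    -0.2124
#> ar2     -0.3002   0.1681    -0.6297     0.0293
#> sma1     0.1294   0.2403    -0.3415     0.6004
#> step -3113.4045 574.3226 -4239.0768 -1987.7322
#> ramp -1351.8358 113.8785 -1575.0376 -1128.6340
#> sigma^2 = 341890, log-likelihood = -272.9426
#> AIC = 557.89, AICc = 560.89, BIC = 567.22

ljung_box(fit, lags = 24)
#> Ljung-Box test: Q = 15.975 on 21 df (24 lags, fitdf = 3), p = 0.7711

head(effect_summary(fit), 2)
#>  horizon    date   effect     lower     upper cumulative
#>        0 2014-01 -4465.24 -5511.57 -3418.91   -4465.24
#>        1 2014-02 -5817.08 -6828.10 -4806.05  -10282.32
```

Reading: the restriction is associated with an immediate, sustained drop
of about 3113 dispensings (95% CI −4239 to −1988) and a further decline of
about 1352 dispensings per month (−1575 to −1129). The residuals pass the
Ljung-Box white-noise check (p = 0.77 at 24 lags), so the model adequately
captures the autocorrelation. The combined effect in the first post-policy
month is step + ramp ≈ −4465 dispensings relative to the counterfactual;
effects accumulate thereafter. (The generator injected a step of −3285 and
a ramp of −1397: both estimates cover their truths.)

The same analysis from the shell:

```sh
itsarima report --input inst/extdata/quetiapine_synthetic.csv \
  --config inst/extdata/interventions.yaml --d 1 --D 1 --out-dir run1
```

which writes `report.json`, `report.md`, the order-search trace, the
effect table and the observed/counterfactual trajectories.

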