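---
title: "Monitoring autocorrelated mortality series: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring autocorrelated mortality series: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spcmort)
```

## The problem

Statistical process control treats a monitored statistic — here the monthly
mean hospital mortality of an intensive-care unit — as "in control" when it
varies only by common causes, and flags special causes when the statistic
leaves control limits. The classical machinery (Shewhart and EWMA charts,
three-sigma limits, average run lengths) assumes independent observations.
Monthly ICU mortality series violate that assumption in three distinct ways:

* **autocorrelation**, visible in ACF/PACF displays out to long lags;
* **seasonality** with a 12-month period (winter mortality excess);
* **volatility**: the variance of the series itself clusters in time
  (conditional heteroscedasticity), on top of a slow secular decline in
  mortality.

Applying iid-based control limits to such a series inflates the false-alarm
rate: excursions that are ordinary behaviour of an autocorrelated, volatile
process get flagged as special causes. `spcmort` implements both halves of
the argument: the naive charts (so the over-signalling can be demonstrated
and quantified) and the time-series remedy — model the series, verify the
residuals are white noise, and chart the residuals instead.

## Risk adjustment

Raw mortality confounds performance with case-mix. The risk model is a
random-coefficient logistic regression: for patient $j$ at site $i$ with
severity score $s_{ij}$ (an APACHE-III-like scalar, taken as given),

$$\operatorname{logit}\Pr(\text{death}) = (\beta_0 + u_{0i}) +
  (\beta_1 + u_{1i})(s_{ij} - \bar s), \qquad
  (u_{0i}, u_{1i}) \sim N(0, \Sigma)$$

with unstructured $2\times2$ covariance $\Sigma$. `fit_risk_model()`
estimates this by Laplace approximation (`lme4::glmer`); the contract is
recovery of the fixed effects and covariance, not bitwise agreement with any
particular quadrature implementation. Severity is centred at the cohort mean
and the centring constant is stored in the model so predictions are
reproducible. A single-site cohort degenerates to ordinary logistic
regression (flagged with a warning); a cohort with only one outcome value is
refused. `predict_expected()` gives each patient an expected death
probability, using zero random effects for sites unseen at fit time, and the
monthly means of these probabilities form the *expected* (risk-adjusted)
series. Calibration and discrimination are summarised by the
Hosmer–Lemeshow statistic over predicted-risk quantile groups (10 by
default, ties kept in one group) and the rank-statistic (Mann–Whitney) AUC
with ties averaged. No seasonal covariates enter the risk model; the
seasonality is left in both the raw and expected series deliberately, since
characterising it is the point.

## Series construction and eligibility

`build_monthly_series()` aggregates patient rows into per-site monthly
series; months without patients are masked missing. For the expected series
the within-month standard error of the mean predicted probability
($\mathrm{SD}(p)/\sqrt{n_t}$) is stored alongside, because it later defines
the reference-chart limits. Two continuity screens decide what a series can
support (`screen_eligibility()`):

* autocorrelation assessment to lag 40 needs 41 gapless usable months —
  for raw series, months with zero mortality are excluded alongside missing
  months (a zero raw rate is uninformative for a ratio-scale rate series);
  for expected series only missing months are excluded;
* seasonal assessment needs at least 72 gapless months, excluding missing
  months only, for both kinds.

Continuity is assessed **from the series start forward**: the screening run
is the maximal eligible run beginning at the first eligible month. When a
series is extracted for modelling (as in `run_exemplar()`), the *longest*
eligible run is used instead; the two conventions are implemented separately
because a screen asks "has this site reported continuously?" while the
analyst just wants the largest usable sample.

## Diagnostics

The diagnostic battery mirrors standard Box–Jenkins practice:
correlograms (sample ACF with the lag-0-variance denominator, PACF by
Durbin–Levinson, $\pm1.96/\sqrt n$ white-noise bounds), the Ljung–Box
portmanteau $Q$ with the small-sample correction and a fitted-parameter df
reduction for residual series, a Bartlett-type cumulative-periodogram test
(KS distance of the normalised cumulative periodogram from the uniform
line), the augmented Dickey–Fuller regression with embedded Dickey–Fuller
$\tau$ quantile tables interpolated in sample size and probability
(Schwert's rule $\lfloor 12(n/100)^{1/4}\rfloor$ for the default lag
order), Shapiro–Wilk with moment skewness and *non-excess* kurtosis
(normal $\to$ 3), classical additive decomposition (centred $2\times12$
moving-average trend, re-centred period means, missing trend/remainder on
the first and last six months), and lag-plot pair tables.

## Time-series models

`detrend_linear()` removes a deterministic linear trend by OLS — the
appropriate treatment when unit-root tests reject against trend
stationarity, as they do for the series this package targets.
`fit_arma()` estimates sparse-lag ARMA models: only the named lags are
free, everything between is pinned to zero, so a model like
AR{24} + MA{1, 15, 17} has four mean parameters rather than forty-one. A
multiplicative seasonal factor $(1-\Phi_1 B^{12})$ is available for the
smoother expected series, written in the standard multiplicative form
because that matches the two printed lag-1 coefficients such models report.
Estimation defaults to conditional sum of squares with zero-initialised
pre-sample innovations (exact-likelihood refinement via `method = "CSS-ML"`
or `"ML"`); AIC and BIC are computed from the reported likelihood with the
parameter count including the innovation variance, and both were verified
against a brute-force Gaussian likelihood evaluation in the test suite.

`fit_garch()` adds the variance equation
$$\sigma^2_t = \gamma_0 + \textstyle\sum_{i=1}^{m}\gamma_i\epsilon^2_{t-i}
  + \sum_{j=1}^{k}\delta_j\sigma^2_{t-j}$$
estimated jointly with the sparse ARMA mean by conditional maximum
likelihood, with normal, Student-$t$ or generalised-error standardised
innovations. Numerical choices that matter:

* pre-sample $\epsilon^2$ and $\sigma^2$ are initialised at the sample mean
  of the squared mean-equation residuals;
* variance parameters are kept nonnegative by log transforms during
  optimisation (Nelder–Mead then BFGS polish), so
  $\sum\gamma + \sum\delta \ge 1$ — an integrated-variance process, which
  real mortality series can produce — is *permitted* and flagged rather
  than refused;
* standard errors come from the outer product of numerically evaluated
  per-observation scores (OPG), which keeps the SE convention consistent
  with the recovery tests;
* the joint Wald test of the variance parameters uses that OPG covariance.
  Under an iid null the tested parameters sit on the boundary of the
  parameter space, which makes the chi-square reference conservative — and
  with $k \ge 1$ the null is additionally unidentified ($\delta$ is free
  when $\gamma = 0$), so null-calibration checks use the ARCH-only fit.

One-step forecasts use information to $t-1$; the one-step standard error is
the innovation SD for homoscedastic ARMA fits and the conditional SD
$\sigma_t$ for GARCH fits.

## Control charts

All charts share the EWMA recursion $z_i = \lambda x_i + (1-\lambda)z_{i-1}$
and the variance
$\sigma^2_{z_i} = \sigma_x^2\,\tfrac{\lambda}{2-\lambda}(1-(1-\lambda)^{2i})$.
The chart family:

* **fixed / time-varying EWMA** (`ewma_chart()`): limits at
  $\pm L\sigma_{z_i}$ (time-varying, narrower early) or the asymptote
  (fixed); $z_0$ defaults to the target;
* **moving centre-line EWMA** (`moving_centerline_chart()`): for
  autocorrelated data, the centre line at $t$ is the one-step EWMA
  prediction $z_{t-1}$ and the limit half-width is three times the
  root-mean-square one-step prediction error;
* **risk-adjusted reference chart** (`reference_3se_chart()`): raw series
  monitored against $\text{expected}_t \pm 3\,SE_t$. The "3 SE of the
  expected series" is interpreted as the monthly standard error of the mean
  predicted probability — the single most consequential interpretation in
  the package, surfaced as `se_mode = "monthly"` with a
  `"series_sd"` alternative (three times the SD of the expected series);
* **residual EWMA** (`residual_ewma_chart()`): a standard EWMA of model
  residuals (target 0, SD of the residuals as $\sigma_x$), valid because a
  mean shift in the original series is transmitted to the residuals;
* **forecast-error chart** (`forecast_error_chart()`): observations against
  $\hat x_t \pm 3\,\widehat{se}_t$; for GARCH fits the limits breathe with
  $\sigma_t$.

The smoothing constant, where not supplied, is the in-sample SSE-optimal
value (`optimize_lambda_sse()`): the EWMA is started at the sample mean,
one-step squared prediction errors are summed from the second observation
with the first ten errors discarded as warm-up, and ties go to the smallest
$\lambda$. The warm-up discard is deliberate: without it the start-up
transient dominates the criterion and the known IMA(1,1) correspondence
(optimal $\lambda = 1-\theta$) is not recovered; with it, iid data select
the smallest grid value and IMA(1,1) data with $\theta = 0.7$ select
$\lambda \approx 0.30$, both verified in the test suite.

A note on what over-signalling does and does not require: a misspecified
*forecast* chart whose variance is estimated from the monitored series
itself (for example a white-noise fit to an AR process) still covers the
process marginally and keeps a near-nominal pointwise rate. The
false-positive inflation this package demonstrates comes from limits that
reference a *smoother* process than the one being monitored — the
risk-adjusted reference chart — which is exactly the contrast the
acceptance suite measures.

## Run-length computation and chart design

`arl_markov()` discretises the EWMA statistic over the asymptotic control
interval into an odd number of equal states (201 by default) and solves the
fundamental-matrix equations of the transient Markov chain; transition
masses are exact normal-CDF integrals over each state interval. With
$\lambda = 1$ this collapses to the Shewhart geometric run length
$1/(2(1-\Phi(L)))$, which the implementation reproduces to well under 1%.
Zero-state run length (statistic started at the target) is the design
convention; `initial = "steady"` instead averages over the in-control
stationary distribution conditioned on no alarm, the right quantity for the
delay in detecting a shift that arrives after the chart has settled.
`arl_montecarlo()` is the stochastic counterpart and independent check.

`optimal_lambda()` designs a chart for a stated shift $\delta$ (in
process-SD units): for each $\lambda$ on a 0.01-step grid it solves the
limit width $L$ by bisection so the in-control ARL equals the requirement
(370 by default) within 0.5%, then picks the $\lambda$ minimising the ARL
at $\delta$. `scenario_design()` converts a percentage increment of a
mortality mean into SD units first. The ARL-vs-$\lambda$ profile near its
minimum is very flat (fractions of a percent across neighbouring grid
values), so alternative software conventions — fixing $L = 3$ and letting
the in-control ARL float, steady-state rather than zero-state run lengths —
can report neighbouring $\lambda$ values that are operationally equivalent
designs; the profile is returned with every design so this can be audited.

## The synthetic-data generator

No patient-level ICU database is distributable with a package like this, so
every stage is exercised on synthetic data whose defaults emulate the
structure the methods assume: 137 sites, about 3,600 patients per site over
180 months (≈491,000 records), site random intercepts (SD 0.5) and severity
slopes (SD 0.005) for a truncated-normal severity score (mean 52, SD 28,
slope 0.04 per unit), a logit-scale trend of −0.002 per month centred at
mid-series, and a period-12 sinusoid of amplitude 0.1 on the logit scale.
The fixed intercept default (−2.3236) was calibrated once, by Monte-Carlo
integration over the random effects and case-mix at these defaults, so that
marginal mortality is 14.07%; the trend is centred so it does not move that
marginal mean. Trend and seasonal amplitudes are choices for testability —
the source analyses demonstrate but never parameterise them.

`generate_structured_series()` simulates sparse-lag ARMA paths with
(G)ARCH innovations (normal, $t$, or generalised-error, all standardised to
unit variance), discarding a 500-step burn-in, then adds mean, linear trend
and a period-12 sinusoid. Monthly patient counts are Poisson, so zero-death
months arise naturally and exercise the raw-series continuity screen.

What the generator does *not* emulate: calendar effects beyond month
indices, case-mix drift, reporting artefacts, inter-site correlation, and
month-to-month dependence of patient counts. Passing tests therefore show
that the methods behave as designed on processes with the assumed
second-order structure — not that real mortality series satisfy those
assumptions.

## Problem sizes in the test suite

The suite favours a few deep parameterised checks per operation. Recovery
simulations use 100 replicates at series length 3,000–4,000 for the ARMA
and GARCH coefficient checks, 12 replicates of a 30-site × 900-patient
panel for the mixed-model fixed effects, and 1,000 replicates for each
null-calibration (type-I) check; run-length calibrations use $2\times10^5$
simulated points or $3\times10^4$ simulated run lengths. These sizes give
Monte-Carlo standard errors comfortably inside the asserted tolerances
while keeping the full suite in the low minutes on one core.

## Known limitations

* The GARCH estimator is conditional (not exact-likelihood) and its OPG
  standard errors, while self-consistent, are not robust to severe
  innovation misspecification.
* ADF $p$-values are interpolated from quantile tables; between tabulated
  probabilities they are approximate (critical values at 1/5/10% are
  reported alongside).
* The Wald test of variance parameters is conservative at the boundary;
  likelihood-ratio or score alternatives are not implemented.
* No CUSUM, VLAD, funnel-plot, DF-GLS, STL, automatic order search, or
  multivariate (vector-autoregressive / multivariate GARCH) extensions.
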