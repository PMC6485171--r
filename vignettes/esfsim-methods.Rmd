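---
title: "Modelling primary-care coverage scenarios and avoidable mortality with esfsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling primary-care coverage scenarios and avoidable mortality with esfsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(esfsim)
library(dplyr)
```

## The problem

Brazil's Family Health Strategy (ESF) is a community-based primary-care
programme whose municipal coverage fraction is a policy lever with
well-documented mortality consequences: at full consolidated municipal
coverage, retrospective fixed-effects evaluations attribute reductions of
52%, 21% and 15% to mortality from nutritional deficiencies/anaemia,
infectious diseases and cardiovascular disease respectively — all
ambulatory care-sensitive conditions (ACSCs), deaths considered avoidable
through timely primary care. Long-term fiscal austerity and the possible
termination of the *Mais Médicos* programme (MMP, which places doctors in
underserved municipalities; one doctor is credited with covering 3450
inhabitants) raise the question of what different coverage futures imply
for ACSC mortality and for its distribution across poor and rich
municipalities and between black/pardo and white Brazilians.

`esfsim` implements a municipal-level discrete-time microsimulation of
that question in two stages: (i) construction of a cohort of
municipalities with covariate values through 2030 — here a fully
synthetic, seeded cohort emulating the statistical structure of the real
Brazilian municipal panel — and (ii) prediction of ACSC mortality rates
along four coverage scenarios with Monte Carlo propagation of baseline
and effect-size uncertainty.

## The mortality model

For municipality $i$, year $t$ and outcome stratum $s$ the expected rate
per 100,000 person-years is log-linear:

$$
\log \lambda_{its} \;=\; \alpha_{is} \;+\; \gamma_s\,(t - 2010)
\;+\; \sum_k \log(\beta_{ks})\, x_{kit}
\;+\; c_{it}\, \min(d_{it}/L,\,1)\, \log(\mathrm{RR}^{\mathrm{full}}_s),
$$

where $\alpha_{is}$ are municipality fixed effects absorbing
time-invariant confounding, $\gamma_s$ is the common secular trend,
$\beta_{ks}$ are covariate rate ratios on the panel scales (fractions for
coverage-type covariates, beds per 1000, logs for illiteracy, private
insurance and GDP per capita), $c_{it}$ is ESF coverage, $d_{it}$ the
years of sustained programme presence and $L$ the consolidation lag
(default 4 years). The bilinear coverage-duration ramp passes exactly
through the two printed anchors — no programme, no effect; full coverage
sustained at least $L$ years, the full rate ratio — which is all the
source estimates pin down. A categorical parameterization (no effect
below 70% coverage, half the log-effect before $L$ years, the full
effect after) is available for the duration-effect sensitivity axis;
both interpolate the same anchors.

Death counts are Poisson with mean $\lambda_{its} \times$ person-years
$/10^5$. Race-stratified outcomes (black/pardo and white ACSC mortality)
split municipal person-years by the municipal black/pardo population
fraction; age structure is not modelled, so the "standardised" rate
ratio reported by `standardised_rate_ratio()` is the ratio of predicted
stratum rates — a documented simplification.

The overall-ACSC and race-stratum full-coverage rate ratios and all
confidence intervals are not printed in any public table; the defaults in
`default_effect_table()` (overall 0.75, black/pardo 0.69, white 0.85,
with synthetic interval widths) are package choices at plausible
magnitudes and every entry can be replaced through the configuration.
The covariate rate-ratio defaults are likewise synthetic stand-ins,
shared across strata.

## Fixed effects and calibration

`estimate_fixed_effects()` anchors $\alpha_{is}$ so the mean model
log-rate over the observation window (2010–2016) equals the observed mean
log-rate, adding half a death to zero-count municipality-years
(continuity correction) and flagging municipalities with no deaths at
all. Log-scale anchoring carries the Jensen bias of
$E[\log \mathrm{Poisson}(\mu)] \approx \log\mu - 1/(2\mu)$, negligible at
realistic municipal death counts; the test suite bounds it explicitly.

`calibrate_secular_trend()` fits $\gamma$ by least squares of log
national mean predicted rates on a log observed series (2010–2015 window
by default), re-anchoring the fixed effects at every candidate so the
trend, not the level, is fitted. Observed rates can be adjusted for
undernotification by a multiplicative factor $\ge 1$ — the correction
method used for the real series is not documented, so a multiplicative
stand-in is the package's explicit choice, defaulting to 1 in synthetic
mode.

## The synthetic cohort

`generate_cohort()` emulates the features of the real panel the analysis
relies on, at a desk scale of 500 municipalities by default (the
full-scale 5507 is supported):

* **Cross-sectional moments.** Covariate levels in 2015 are drawn from
  moment-matched distributions hitting the published municipal
  means/standard deviations exactly in expectation: Beta for fraction
  covariates (which also guarantees $[0,1]$ without clipping — the reason
  this parameterization was chosen over a logit-normal), Gamma for
  non-negative ones (hospital beds), Normal on the stored scale for
  log-transformed ones. 2016 ESF coverage has mean 0.804, sd 0.235.
* **Histories.** Each municipality-covariate series follows an exact
  exponential trajectory around its 2015 anchor with multiplicative
  log-normal noise (sd 0.05), so the forecasting stage has a recoverable
  ground truth. Mean trend rates are package choices giving realistic
  decade directions (poverty and illiteracy falling, urbanisation, GDP
  and private insurance rising). ESF coverage ramps up linearly from 25%
  of its 2016 level in 2000, reflecting the programme's scale-up.
* **MMP doctors** appear from 2013 with a per-capita Poisson intensity
  increasing exponentially in the municipality's poverty rank (strength
  2 by default, i.e. clearly concentrated in poor municipalities; 0
  removes the association). The allocation law is a package choice — the
  programme is only described as targeting underserved areas.
* **Deaths** are generated from the mortality model itself with
  $\alpha_{is} = \log(\text{baseline rate}_s) - x_{i,2010}'\log\beta +
  \mathcal{N}(0, 0.3)$, so the generating parameters are a recoverable
  ground truth. Baseline 2010 stratum rates (overall 100, nutritional
  3.5, infectious 12, cardiovascular 50, black/pardo 115, white 85 per
  100,000) are package choices at realistic Brazilian under-70
  magnitudes, with black/pardo above white.

What the generator does **not** emulate: spatial correlation, migration,
age structure, reporting heterogeneity, and the real panel's
cross-covariate correlation structure beyond what the shared poverty
gradient induces. Passing tests therefore demonstrate the correctness of
the machinery and the qualitative scenario logic, not the reproduction of
the real national estimates — those require the undeposited real panel
and the complete effect-size table of the source evaluation.

## Covariate forecasting

Covariates are extrapolated from 2011 with
$v(t) = \mathrm{floor} + (v_{2010} - \mathrm{floor})\,
e^{-\lambda (t-2010)}$, where $\lambda$ is the least-squares slope of
$\log(v - \mathrm{floor})$ on year over all eleven 2000–2010 points —
a regression fit rather than an endpoint ratio, because endpoint-only
fits are fragile to noise. $\lambda$ is sign-free (urbanisation and GDP
grow), fraction covariates are capped at 1, and non-positive series fall
back to a flagged flat trend. Log-scale covariates are fitted on the
exponentiated scale and re-logged. Bolsa Família coverage is observed
through 2016 and re-anchored there; the other socioeconomic covariates
are extrapolated from 2011, mirroring the availability structure of the
real data. Municipal poverty is then recalibrated so its national
population-weighted mean follows the recession-era path (13.8% in 2015,
18.4% in 2020, 12.0% in 2030, linearly interpolated): each municipality
is rescaled multiplicatively and clipped, iterating to a fixed point. The
proportional allocation of the national shock across municipalities is a
documented choice — the original allocation rule is not stated.

## Scenarios

All four scenarios transform the observed 2016 coverage:

* `status_quo` freezes coverage (and effectiveness) at 2016 levels.
* `austerity` multiplies 2016 coverage by a common decline path,
  log-linearly interpolated through anchors calibrated so the cohort
  means reproduce the forecast declines (66.5% mean coverage in 2020,
  37.8% in 2030, from 80.4%). A severity exponent (`path^severity`)
  drives the dose-response sensitivity axis. The multiplier applies to
  total coverage, including any MMP contribution.
* `austerity_mmp_end` additionally removes the MMP contribution
  (doctors × 3450 / population, capped by total coverage) instantaneously
  in the termination year (2019); no phase-out profile is published, so
  instantaneous removal is the default.
* `uhc` ramps coverage linearly to 100% in every municipality by 2030.
  The published mean trajectory reaches 95.6% by 2020, implying a
  faster-than-linear early ramp whose shape is unspecified; the linear
  ramp is the package's documented divergence, and only the 2030
  endpoint is treated as binding.

Pointwise dominance `uhc ≥ status_quo ≥ austerity ≥ austerity_mmp_end`
holds by construction and is property-tested.

## Monte Carlo engine

Per draw, `run_simulation()` (10,000 draws in the study design; a few
hundred suffice at desk scale) resamples

1. every rate ratio from a Normal on $\log \mathrm{RR}$ centred at the
   point estimate with $\sigma = (\log\mathrm{hi} - \log\mathrm{lo})/
   (2 \times 1.96)$ — the log scale keeps rate ratios positive; the
   source description does not fix the scale, so a natural-scale option
   is exposed by flag;
2. observed baseline deaths as Poisson around the recorded counts,
   re-anchoring the fixed effects,

then evaluates the deterministic model along every scenario trajectory.
With both switches off the engine reduces exactly to the deterministic
prediction (tested to 1e-12). Summaries report means and the 2.5%/97.5%
draw quantiles. "Mean municipal rate" is the unweighted mean over
municipalities (population weighting is available as an option); excess
deaths are population-weighted by construction; scenario ratios are means
of per-draw ratios, so reciprocity holds draw by draw.

## Inequality metrics

Municipalities are stratified into quintiles of the 2010 poverty
distribution (equal municipality counts, ties broken by id order,
assignment fixed thereafter). The concentration index uses the standard
health-economics form $C = 2\,\mathrm{cov}_w(y, R)/\mu$ with
population-weighted fractional ranks ordered poorest-first (midpoint
convention) — the original index formula and weighting are not
published, so this convention is adopted and cross-checked against an
independent brute-force implementation in the tests. Quintile rate
differences and the black/pardo-vs-white rate ratio are computed per
draw and summarised like every other quantity.

## Validation and sensitivity

`internal_validation()` refits the generating fixed-effects Poisson
regression on simulated panels. The fitter profiles the municipality
intercepts out of the likelihood analytically and Newton-iterates on the
slope block only, with the slope covariance taken from the Schur
complement of the full Hessian — the exact dummy-variable MLE without
materialising hundreds of indicator columns (the tests verify equality
with `glm` on small instances). On noise-free panels every coefficient is
recovered to numerical tolerance; under Poisson noise the 95% Wald
intervals cover at their nominal rate (checked over 200 replicate panels
of 500 municipalities × 14 years). Identification requires within-
municipality coverage variation: a frozen-coverage (status quo) panel
makes the coverage term collinear with the fixed effects, and the fitter
reports exactly that, so validation panels are simulated under a
time-varying scenario such as `austerity`.

`external_validation()` regresses any supplied observed national series
on the predicted one (slope, intercept, $R^2$, fraction of observations
inside the predicted 95% band); the derivation of an ACSC series from
all-cause mortality sources is out of scope, the series is consumed
ready-made.

`run_sensitivity()` reruns the pipeline under named variants of five
axes (decline magnitude, duration effect, poverty-stratified
effectiveness, recession path, secular trend) with a shared seed.
Secular-trend variants shift only the prediction model, never the
synthetic world, so common trend shifts cancel exactly from
between-scenario rate ratios — the invariance the sensitivity analysis
is meant to demonstrate. Decline-magnitude variants are checked for
dose-response ordering.

## Numerical choices and problem sizes

Defaults chosen once and used throughout: 500 municipalities and 500
draws for the shipped configuration (full scale supported); duration lag
4 years; coverage effect parameterization continuous; effect sampling on
the log scale; trend search interval $[-0.2, 0.2]$ with `optimize()`
tolerance 1e-9; Newton tolerance 1e-10 on the score with step halving;
continuity correction 0.5 deaths on zero-count years; calibration
rescale iterated at most 8 passes. The test suite uses smaller cohorts
(20–500 municipalities) matched to what each property needs.

## A worked run

```{r, eval = FALSE}
cfg <- default_config()
cfg$generator$n_municipalities <- 200L
cfg$simulation$n_draws <- 200L
bundle <- run_pipeline(cfg)

bundle$ratios          # scenario rate ratios vs status quo, 2020/2030
bundle$excess          # cumulative excess deaths 2017-2030
autoplot(bundle$simulation)
```

## Known limitations

* The unit is the municipality-year; within-municipality individuals,
  ages and migration are not modelled.
* Effect sizes are inputs, not estimates; nothing is learned from data
  about them beyond the secular trend.
* Prediction uncertainty is Poisson + effect-size sampling; covariate
  forecast uncertainty is not propagated (matching the two-stage study
  design).
* The default synthetic parameters reproduce the qualitative structure
  of the Brazilian panel, not any specific national estimate.
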