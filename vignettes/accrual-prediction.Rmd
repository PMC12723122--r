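---
title: "Gamma-Poisson accrual prediction: model, choices, and rationale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gamma-Poisson accrual prediction: model, choices, and rationale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesaccrual)
```

This vignette records the modeling and implementation decisions behind
`bayesaccrual` and the reasoning for each, so that users can judge whether
the defaults fit their trial.

## Model and assumptions

Enrollment counts per quarter are modeled as conditionally independent
Poisson variables. For quarter $j$ with exposure $t_j$ (in quarter units)
and count $m_j$:

$$m_j \mid \lambda \sim \text{Poisson}(\lambda\, t_j), \qquad
  \lambda \sim \text{Gamma}(\alpha, \beta),$$

where the gamma distribution uses the **rate parameterization** throughout
the package: mean $\alpha/\beta$, so $\beta$ carries the units of exposure
(quarters) and the conjugate update is a literal bookkeeping of data,

$$\lambda \mid m_{1:J} \sim
  \text{Gamma}\!\Big(\alpha + \sum_j m_j,\; \beta + \sum_j t_j\Big).$$

The seasonal model replaces the single $\lambda$ by four rates
$\lambda_s$, one per meteorological quarter (summer, fall, winter,
spring), each with an independent $\text{Gamma}(\alpha, \beta)$ prior and
each updated by its own season's counts and exposure. A season with no
observed quarters simply retains its prior; `posterior_summary()` flags
such seasons with `prior_only = TRUE` rather than failing.

Assumptions to be aware of: counts are conditionally independent across
quarters given the rates (no autocorrelation beyond seasonality), rates
are constant within a season across years (no trend or learning-curve
effect), and sites are pooled (no hierarchical center structure).

## Prior elicitation and the meaning of `confidence_p`

`elicit_prior(target_enrollment, planned_quarters, confidence_p)` sets

$$\alpha = \frac{N}{Q}\, p, \qquad \beta = 1 \cdot p .$$

The prior mean is exactly the planned rate $N/Q$, and $p \in (0, 1]$ is
interpretable as prior sample size: the prior contributes $p$ quarters of
pseudo-exposure and $p \cdot N/Q$ pseudo-participants to the posterior. A
value of $p = 0.5$ — used in the worked analyses — weighs the planning
assumption as half of one observed quarter, so even a single quarter of
real data dominates it. This keeps the prior from propping up an
optimistic plan while still regularizing early, data-poor posteriors.

## Why direct conjugate sampling instead of MCMC

The posterior is an exact gamma distribution in both models, so posterior
"draws" are i.i.d. `rgamma()` samples: no burn-in, no convergence
diagnostics, no Monte-Carlo autocorrelation. MCMC machinery would add
failure modes without changing any distribution. Simulation-based
summaries (quantile credible intervals from 10,000 draws) are still
offered alongside closed forms (`posterior_summary(method =
"monte_carlo")` vs `"analytic"`) because finite-draw quantiles are how
such intervals are typically reported, and the package's tests verify the
two agree within Monte-Carlo error.

## The predictive simulation and the shared-draw scheme

`predict_total()` simulates the total enrollment at a horizon by drawing,
per replicate, **one rate value per rate parameter** and sharing that
value across all of the replicate's future quarters, then adding Poisson
counts to the observed total. The alternative (`scheme = "per_quarter"`)
redraws the rate for every future quarter.

The distinction matters. With $T$ future unit quarters and posterior mean
$\mu$ and variance $\sigma^2$:

* shared draw: $\text{Var}(\text{future total}) = T\mu + T^2\sigma^2$;
* per-quarter draws: $T\mu + T\sigma^2$.

The shared scheme treats the unknown rate as one persistent fact about the
trial, which is the correct accounting when the Poisson rate is a fixed
unknown rather than quarter-to-quarter noise; per-quarter redrawing makes
rate uncertainty average out over the horizon and yields intervals that
are too narrow at long horizons. Concretely, for a posterior
$\text{Gamma}(145.25,\, 26.5)$ and 10 future quarters the shared scheme's
variance is $10\mu + 100\sigma^2 \approx 75.5$ versus $10\mu + 10\sigma^2
\approx 56.9$ per-quarter — about a 15% difference in interval width that
grows linearly in the horizon. The shared scheme is the default; the
per-quarter scheme is kept for sensitivity analysis.

Under the seasonal model the draw is shared per season, so the variance
is $T\mu + \sum_s T_s^2 \sigma_s^2$ — between the two homogeneous
extremes. One consequence worth knowing: when all four seasonal posteriors
are identical, the seasonal predictive matches the homogeneous one exactly
under the per-quarter scheme but has smaller variance under the shared
scheme, because four independent season draws diversify the rate risk that
a single shared draw concentrates.

## The season calendar and partial quarters

Quarters are meteorological and anchored mid-month: summer starts June 16,
fall September 16, winter December 16, spring March 16 (a different
anchoring, e.g. for the southern hemisphere, can be supplied via
`season_calendar()`). When monthly tables are aggregated with
`quarterize()`, a month belongs to the quarter containing its 16th day, so
whole months are never split.

Two defaults govern edge quarters:

* `full_first_quarter = TRUE` with `partial_threshold = 0.5`: if the trial
  opened partway into its first quarter and covers **less than half** of
  that quarter's span, the quarter is dropped and its enrollment is
  recorded in the series' `excluded_count` attribute instead of biasing
  the rate of a nearly-empty exposure window. If it covers at least half,
  it is kept with its fractional duration.
* A trailing partial quarter is kept and prorated by the number of months
  present (duration $k/3$ for $k$ observed months).

The 0.5 threshold is a judgment call: below half a quarter, the
enrollment-per-exposure ratio in the stub is dominated by start-up effects
(staggered site activation) that neither model represents.

## The `observed_total` convention

Predictive totals answer "how many participants will the trial have
enrolled", so they include participants excluded from the *modeling*
(e.g. the dropped partial first quarter): `predict_total()` defaults
`observed_total` to modeled counts plus `excluded_count`. The posterior
for the rate, by contrast, uses only modeled counts over modeled exposure.
These are different questions and the package keeps their bookkeeping
separate.

## Model comparison: DIC with the posterior-mean plug-in

`compute_dic()` uses the classical construction
$\text{DIC} = \bar{D} + p_D$ with
$p_D = \bar{D} - D(\bar{\lambda})$, where $\bar{D}$ is the posterior mean
deviance over draws and $D(\bar{\lambda})$ evaluates the deviance at the
posterior mean rate(s) — the standard plug-in for this family, where the
posterior mean is the Bayes estimator under squared error and the deviance
is convex in $\lambda$ on the observed-data scale. The deviance includes
the full $\log(m_j!)$ normalizing terms so that $p_D$ is interpretable;
empirically $p_D$ tracks the number of informed rates (about 1 for the
homogeneous model, about 4 for the seasonal model with all seasons
observed). DIC differences, not levels, are meaningful; the package's
tests exercise only the ranking behavior (the seasonal model wins on
strongly seasonal data, the homogeneous model on rate-homogeneous data).

## Rolling internal prediction

`rolling_evaluation()` refits on quarters $1..k$ for every $k$, predicts
the remaining quarters, and reports, against the realized final total
$M$: $\text{Bias}_k = \bar{Y}_k - M$, $\text{SD}_k$ of the replicate
totals, and $\text{RMSE}_k$, which satisfy
$\text{RMSE}^2 = \text{Bias}^2 + \text{SD}^2 (R-1)/R$ with $R$ replicates.
This is an *internal* audit — the "future" data were available when the
model was specified — but it shows how quickly the prior-data conflict
(bias at small $k$) washes out and how fast the predictive tightens.

## The synthetic generator and calibration logic

`generate_series()` produces Poisson (optionally gamma-overdispersed)
quarterly counts from known seasonal rates — the same process the model
assumes, which is the point: it supports *parameter-recovery* validation,
not realism claims. `recovery_experiment()` runs repeated
generate-fit-summarize cycles and reports per-season credible-interval
coverage, absolute error, and width. With `resample_rates = TRUE` the true
rates are redrawn from the prior each replication, which makes nominal
coverage *exact in expectation* for a correctly specified model — a sharp
calibration target, used in the test suite with a band of
$[0.92, 0.98]$ around the nominal 0.95 at 500 replications. Fixed-rate
recovery (rates supplied by the user) is also available for studying
prior-data conflict, where coverage is not guaranteed to be nominal.

## Problem sizes used

The package's own analyses and tests use 10,000 posterior or predictive
draws for reported summaries (matching the reporting convention for the
trial-scale results), up to $3\times 10^5$ draws for moment-law checks,
100–500 replications for calibration and model-ranking experiments, and
series of 12–40 quarters. These sizes were chosen so that Monte-Carlo
error is small relative to the effects being checked; all are arguments,
not constants, and can be scaled up.

## Limitations

* No trend: a rate that drifts within a season across years is attributed
  to noise.
* No hierarchy: multi-center trials are pooled; center-level gamma-Poisson
  extensions are out of scope.
* Independence: holidays, competing trials, or recruitment pushes induce
  correlation the model ignores.
* DIC is reported because it is the conventional criterion for this model
  family; it is not a substitute for the rolling predictive audit.
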