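---
title: "Estimating the effect of high bed occupancy on 14-day mortality with marginal structural models"
author: "occmsm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the effect of high bed occupancy on 14-day mortality with marginal structural models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occmsm)
library(data.table)
set.seed(1)
```

## The problem

Whether days of unusually high bed occupancy (capacity utilization) cause
excess short-term in-hospital mortality is a longitudinal causal question
with a twist: the obvious adjustment variables are themselves caught up in
the causal process. Daily patient turnover and the clinical complexity of
the ward influence how full the hospital is *and* are influenced by how full
it was yesterday; unmeasured processes such as staffing drive both turnover
and deaths. This structure — past exposure affecting the confounders of
future exposure — is treatment-confounder feedback (TCF). Conditioning on
such confounders in an outcome regression blocks part of the causal pathway
and opens collider paths, so conventional regression cannot recover the
effect no matter which covariates it adjusts for. The standard remedy is a
marginal structural model (MSM): a pooled logistic model for the daily death
hazard, fitted with stabilized inverse-probability-of-treatment weights
(IPTW) so that, in the weighted pseudo-population, the exposure is
unconfounded by the measured time-varying covariates.

`occmsm` implements that analysis end to end for patient-level inpatient
episode records, and ships a synthetic multi-hospital generator with a known
causal truth so every estimator in the package can be validated against a
computable oracle.

## From episode records to the analysis table

The cohort pipeline follows administrative-data conventions:

* **Inclusion filters.** Episodes admitted before the study year or within
  its final two weeks are excluded, so each retained patient has a complete
  14-day exposure and outcome window (`apply_inclusion_filters()`).
* **Daily series.** A patient occupies a bed on the days
  `[admission, discharge)`; same-day stays count on the admission day, and a
  death day is always a bed day. Capacity utilization on day $d$ is
  $CU_d = 100\,\mathrm{census}_d / \max_{d'} \mathrm{census}_{d'}$ — each
  hospital is normalized by its own busiest day, because administrative data
  carry no bed counts. Patient turnover is
  $PT_d = 100\,(\mathrm{admissions}_d + \mathrm{discharges}_d)/\max_{d'}
  \mathrm{census}_{d'}$, and the daily mean PCCL (patient clinical
  complexity level, 0–4) summarizes the in-house casemix
  (`build_daily_series()`). The phrase "day with the most admitted patients"
  admits two readings; the peak *census* is the default because it yields a
  bounded 0–100 utilization scale, and `peak = "admissions"` provides the
  alternative.
* **Exposure.** A hospital-day is *high exposure* when its utilization
  reaches the hospital's own 85th-percentile threshold (type-7 interpolated
  quantile, ties exposed). Hospital-specific percentiles, rather than a
  single absolute cut-off, respect the heterogeneity of hospital size and
  case mix and protect positivity: every hospital has roughly 15% exposed
  days by construction (`derive_threshold()`).
* **Person-days.** Each episode becomes one row per at-risk stay-day
  ($t = 1, \dots, \min(\text{LOS}, \text{death}, 14)$) carrying the day's
  exposure $A_t$, the cumulative exposed-day count
  $\mathrm{cumA}_t = \sum_{s \le t} A_s$, the hospital-day confounders
  $L_t = (PT_t, \overline{\mathrm{PCCL}}_t)$, baseline covariates $V$, and
  the death indicator $Y_t$ (`expand_person_days()`). Whether the death
  day's own exposure counts is not decidable from first principles; the
  default includes it, and `exposure_lag = TRUE` switches to the
  previous-day convention.

## Weights and the outcome model

Stabilized weights are built from two pooled logistic exposure models
(`fit_exposure_models()`):

$$ sw_i(t) = \prod_{s \le t}
   \frac{P(A_s = a_{is} \mid \bar A_{s-1}, V_i, s)}
        {P(A_s = a_{is} \mid \bar A_{s-1}, L_s, V_i, s)} $$

The numerator conditions on exposure history (previous-day flag, lagged
cumulative count), the stay-day index (categorical) and baseline covariates;
the denominator adds the time-varying confounders. Under correct
specification $E[sw] = 1$; the package flags a mean deviating from one by
more than 0.05 as a misspecification warning, and `truncate_weights()`
winsorizes at the 1st/99th percentiles for the usual sensitivity analysis.
Because bed occupancy is an accumulating process, the previous day's
*continuous* utilization level predicts today's exposure far better than the
binary flag history alone; `default_denominator_formula(cu_lag = TRUE)`
offers that enriched denominator. It buys stronger confounding control at
the price of sharper fitted probabilities and heavier weight tails, so the
paper-style denominator remains the default.

The outcome model (`fit_pooled_logistic()`) is a weighted pooled logistic
regression of the daily death indicator on the exposure term — cumulative
exposed days by default, the daily binary flag with `exposure = "short"` —
plus weekend admission, hospital type (university reference), comorbidity
class ($<0$ reference), age band (numeric) and sex. Variances are
independence-working-correlation sandwich estimates clustered at the
hospital level (patient level optional), with no small-sample correction,
matching standard GEE output; confidence intervals are normal-theory on the
log-odds scale. The exposure coefficient exponentiates to the causal odds
ratio per additional exposed day.

One modelling choice deserves emphasis: the outcome model includes a
categorical stay-day term by default. Stay length correlates with clinical
complexity, so the at-risk population at later stay-days is sicker; because
cumulative exposure also grows with $t$, omitting the day term loads that
composition drift onto the exposure coefficient (about $+0.07$ on the
log-odds scale in our simulations, measured under *randomized* exposure).
`include_day_term = FALSE` restores the smaller model.

## The synthetic generator and what it emulates

`generate_cohort()` simulates one study year of a multi-hospital system.
Its defaults are calibrated to the population the package is designed for —
a large general-hospital inpatient registry:

| Quantity | Default | Rationale |
|---|---|---|
| Hospitals | 5, expected peak census 175/135/90/65/40, types 1–5 | size gradient from university to small basic; ~22,000 episodes/year |
| Admissions | Poisson, rate = size / mean LOS; weekend factor 0.48 | reproduces a ~16% weekend admission share |
| Length of stay | geometric-type, mean 6.2 days | registry mean stay |
| Covariate mix | 53.4% female; 19 five-year age bands; PCCL and comorbidity-class mixes from registry proportions | descriptive-table composition |
| Mortality intercept | −10.2 | calibrated so 14-day in-hospital mortality ≈ 1.5% |
| Exposure effect | $\beta_A = \log 1.02$ per exposed day | the effect size the analysis targets |
| Occupancy feedback | $\delta = 0.3$ | a high day damps next-day admissions by $e^{-\delta}$ and speeds discharges |
| Staffing process | AR(1), $\rho = 0.8$, innovation SD 0.4; turnover effect 0.25; hazard effect $\gamma = -0.4$ | unmeasured process driving turnover and deaths |
| Severity wave | AR(1), $\rho = 0.9$, innovation SD 0.25; casemix tilt 0.3; LOS effect 0.12 per PCCL level | measured time-varying confounding through daily mean PCCL |

The severity wave is the generator's main *measured* time-varying
confounder: on high-severity days the admitted casemix tilts towards
clinically complex patients, complex patients discharge more slowly (so
severity accumulates into occupancy and hence exposure), and complexity
raises the death hazard. The staffing process plays the unmeasured role from
the study's causal diagram: it accelerates discharges (turnover) and lowers
mortality, and is never visible to the analysis. Occupancy feedback makes
day-$d$ exposure shape day-$(d+1)$ turnover, completing the
treatment-confounder feedback loop encoded in `occupancy_dag()`.

Within a simulated day, admissions arrive, the census (and the exposure
flag) is measured, then end-of-day discharges resolve; a death on day $t$
truncates the stay with the bed freed the next day. During generation the
feedback flag uses an expanding-window percentile of the census (the annual
percentile is unknowable mid-year); the death hazard then uses full-year
percentile flags — the same threshold machinery as the analysis. Because the
analysis recomputes the census from the final records (with death-truncated
stays), its exposure flags can differ from the generator's on a small
fraction of hospital-days near the threshold; with ~1.5% mortality the
effect is negligible, and it is the realistic direction — an analyst never
observes counterfactual bed-days.

Features of real hospital data the generator does **not** emulate:
inter-hospital transfers, within-stay PCCL drift, seasonal and holiday
admission patterns, bed-capacity changes during the year, and discharge as a
competing risk correlated with imminent death. Passing tests therefore
demonstrate the estimators' correctness under the stated mechanism, not the
definitive behaviour of any national registry.

## The oracle and validation

`true_marginal_effect_oracle()` computes the causal estimand by
intervention: it re-simulates the same bed dynamics and covariates, assigns
the hospital-day exposure flags as independent Bernoulli draws at the
observational marginal prevalence (severing every confounder-to-exposure
pathway), runs the same death hazard on the randomized cumulative exposure,
and fits the unweighted pooled logistic across replicate cohorts. The
coefficient is the marginal per-day log-odds ratio the MSM targets; its
Monte-Carlo standard error is the cluster-robust standard error of the
pooled fit (replicate-by-hospital clusters), and an optional `se_tol`
converts insufficient replication into an error.

The test suite uses this oracle in both directions. On unconfounded
configurations (feedback, staffing effect and severity amplitude all zero),
the naive fit recovers $\beta_A$ and its 95% intervals attain nominal
coverage. On a feedback-heavy configuration (severity amplitude 1.0, LOS
effect 0.35 per PCCL level, severity AR coefficient 0.95 — three mid-sized
hospitals over 200 days, with the event rate raised so that estimator bias,
not Monte-Carlo noise, dominates the comparison), the IPTW-weighted MSM is
verified to land closer to the oracle than the unweighted comparator across
200 replicate cohorts. The replicate sizes (a few thousand episodes) and
counts were chosen to keep the whole suite comfortably within a coffee
break on one core while leaving the comparisons decisively powered.

## Numerical conventions and edge cases

* Quantiles everywhere (thresholds, truncation bounds, summary IQRs) are
  type-7 linear-interpolation sample quantiles; ties at the threshold count
  as exposed.
* Printed percentages round half away from zero to one decimal, matching
  publication style (`rate_from_counts()`).
* Weights are validated as positive and finite; observed-exposure
  probabilities within $10^{-9}$ of 0 or 1 raise a positivity warning with
  the affected row count.
* Exposure models refuse to fit a single-level exposure, and report the
  offending term when a non-intercept coefficient exceeds 15 in absolute
  value (a separation heuristic; the intercept is exempt because
  percent-scale covariates legitimately shift it far from zero).
* A hospital with zero peak census yields a constant-zero utilization
  series; empty wards leave the daily mean PCCL as `NA` and such days carry
  no person-day rows.
* Deterministic stages (everything after cohort generation) are exactly
  reproducible; the generator is byte-identical under a fixed seed, with all
  random streams derived from the single master seed.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
cohort <- generate_cohort(cfg)
records <- apply_inclusion_filters(cohort$records)
hd <- build_daily_series(records)
thr <- derive_threshold(hd, 85)
pd <- expand_person_days(records, hd, thr)
models <- fit_exposure_models(pd)
ws <- compute_stabilized_weights(models, pd)
weight_diagnostics(ws)
compare_weighted_unweighted(pd, ws)
```

The same sequence, plus the short-term and truncated-weight variants, the
descriptive table and the threshold sensitivity sweep, is orchestrated by
`run_pipeline()` from a single YAML configuration, writing every
intermediate artifact as CSV/JSON alongside a manifest of the key estimates.

## Known limitations

* The exposure is hospital-wide and shared by all concurrent patients;
  with a handful of simulated hospitals, hospital-level cluster-robust
  variances rest on few clusters and the patient-level option is the more
  stable choice for simulation studies.
* IPTW corrects only confounding that the denominator model can express.
  Bed occupancy accumulates, so confounding routed through the unmeasured
  staffing level's effect on the census *level* (rather than on day-level
  turnover innovations) is only partially removable — an intrinsic limit of
  weighting on daily summaries, shared by any analysis of this design.
* The pooled logistic treats discharge as non-informative censoring within
  14 days; competing-risk structure is out of scope.
* Odds ratios from a non-collapsible model: the oracle targets exactly the
  marginal coefficient defined by its randomized-exposure experiment, which
  at higher event rates can sit slightly below the conditional
  per-day effect used inside the hazard.
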