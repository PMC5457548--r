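---
title: "Methods: new-user cohorts, coverage algebra, IPTW and bootstrap inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: new-user cohorts, coverage algebra, IPTW and bootstrap inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`claimsce` implements, as a reusable pipeline, a comparative-effectiveness
design that is common in pharmacoepidemiology on administrative claims: two
treatment cohorts are formed at drug initiation (a long-acting injectable
antipsychotic versus oral atypical antipsychotics, in the motivating
application), confounding is addressed by inverse-probability-of-treatment
weighting (IPTW) on baseline covariates, and weighted cost differences and
utilization rate ratios over a fixed 12-month window are given bootstrap
confidence intervals. Because real Medicaid claims are proprietary, the
package ships a synthetic claims generator with known ground truth; every
statistical property of the pipeline is demonstrated against that generator,
and this vignette records the modelling choices and their limits.

## The data model

A *claims bundle* holds four tables — patients, enrollment spans, pharmacy
claims (dispense date, days supplied, agent code, paid amount) and medical
claims (service interval, service category, ICD-9-CM diagnoses, paid
amount). Dates are ISO-8601 externally and whole-day integers internally;
all windows are closed intervals of days, because claims carry day
resolution. Agent identity is two-level: the `agent_code` names a product
(used by "same agent" rules) and the `agent_class` an analysis grouping
(the treated index agent, nine named oral atypical agents, typical
oral/LAI and other atypical LAI groupings, anxiolytics, antidepressants,
mood stabilizers, other). The class map is an editable CSV standing in for
the proprietary product dictionaries that real analyses use.

## Cohort construction

The index event for a patient is the earliest date `D` on or after the
accrual start such that one eligible agent has a second qualifying claim in
`[D, D+90]` and no claim for that same agent in `[D-365, D-1]`. The washout
is agent-specific, not class-wide: a patient switching from one oral agent
to another is a new user of the second agent. Treated initiations are
recognizable from pharmacy or medical claims (the injectable is often
provider-administered and billed medically); comparator initiations from
pharmacy claims only. Ties between a treated and a comparator candidate on
the same day are resolved in favour of the treated agent — the paper-style
design needs a deterministic rule, and this one is logged and tested.

Inclusion then requires: two distinct claim dates carrying a schizophrenia
diagnosis (ICD-9 prefix 295) anywhere in the data period; age at least 18
in completed years at index; and enrollment fully covering the 365 days
before and the 365 days from the index date. Windows are fixed 365-day
spans without leap adjustment. The *recently diagnosed* subcohort is ages
18–25 inclusive at index, age being the only proxy available in claims for
recency of diagnosis.

Baseline covariates are computed strictly from the pre-index window:
demographics, insurance eligibility flags, index year and quarter, the
Charlson comorbidity index under Quan's ICD-9-CM coding (with the
complicated-diabetes, metastatic-tumour and severe-liver hierarchy rules),
counts of unique mental-health diagnoses and unique psychiatric agents,
antipsychotic use by type, the baseline any-antipsychotic proportion of
days covered (PDC) as a three-level category (zero, below 0.8, at least
0.8 — the two non-zero levels being shares of patients with any coverage),
antipsychotic polypharmacy, six comorbidity flags, admission counts and
CPI-standardized monthly costs.

## Coverage algebra

All exposure outcomes reduce to an interval union: a fill covers the closed
day interval from its dispense day through `days_supply - 1` days later,
intervals are clipped to the observation window `[0, 364]`, and overlapping
supply is de-duplicated by union rather than shifted forward. The union
("non-overlapping days of supply") reading is reproducible and matches how
PDC denominators are defined; a stockpiling carry-forward variant is a
recognized alternative that the package deliberately does not default to.
Provider-administered injectable claims carry no days-supply field; they are
imputed a 30-day supply (once-monthly dosing), configurably.

- **PDC** is covered days divided by 365; adherence is PDC ≥ 0.8.
- **Persistence** at a gap threshold `g` fails when any uncovered run of at
  least `g` days occurs. Runs include the days before the first covered day
  (relevant for any-antipsychotic persistence) and, by default, the
  terminal run to the window end — a patient who stops at day 60 is not
  "persistent at 12 months". The terminal run is switchable because the
  field is genuinely split on it; both modes are tested against a
  day-array oracle.
- **Continuous exposure** walks index-agent fills in order and ends at the
  supply-end of the first fill whose successor starts more than 90 days
  after that supply-end. The anchor (supply-end versus fill date) is not
  dictated by the phrase "more than 90 days later"; supply-end anchoring is
  the default and fill-date anchoring would be a one-line change.
- **Polypharmacy** bridges per-agent coverage gaps of at most 7 days, then
  asks whether any qualifying agent pair (two distinct antipsychotic
  agents, or an antipsychotic with an anxiolytic/antidepressant/mood
  stabilizer) overlaps for at least 60 consecutive days. Distinct agent
  codes count as distinct agents even when they are oral and injectable
  forms of related products.

Every one of these operations is verified exactly — not approximately —
against an independent 365-slot boolean-array implementation on a thousand
randomized fill sets; the interval code exists for speed and clarity, the
day array for truth.

## Weighting and balance

The propensity score is a maximum-likelihood logistic regression of
treatment on the baseline covariates (IRLS, convergence on the standard
deviance criterion at `1e-8`, at most 100 iterations); fitted probabilities
are clipped to `[1e-6, 1-1e-6]` and a clipped score triggers an
extreme-weight warning. Raw weights are `1/PS` for the treated and
`1/(1-PS)` for the comparator; each weight is divided by the grand mean
over *both* cohorts. Grand-mean normalization is the only convention under
which the weighted cohort sizes sum exactly to the unweighted total, a
conservation law the package enforces to `1e-9` and uses as an invariant
test. Multi-level categoricals enter balance tables one row per level,
compared as binaries with the standardized difference
`100·(p₁−p₂)/√(p̄(1−p̄))`, `p̄ = (p₁+p₂)/2`; continuous covariates use
`100·|m₁−m₂|/√((s₁²+s₂²)/2)`. Weighted summary statistics use the
frequency-weight convention (denominator `Σw`, uncorrected) — standardized
differences are descriptive, so the convention merely has to be fixed and
stated. Balance is declared at 10% in absolute value. No weight truncation
is applied by default; an analysis that needs it can truncate the returned
raw weights before normalizing.

## Effect estimation and the bootstrap

Monthly costs are annual window totals divided by 12, after standardizing
paid amounts to 2015 dollars with the medical-care CPI component (the index
table ships as an editable CSV). The sensitivity scenario discounts branded
pharmacy claims by 23.1%, the mandatory minimum Medicaid rebate for branded
products. The mean monthly cost difference (MMCD) is the treatment
coefficient of a weighted OLS regression on an intercept and the treatment
indicator, which is algebraically the weighted arm-mean difference; the
rate ratio (RR) is the exponentiated treatment coefficient of a weighted
Poisson regression with a log person-time offset, which with the fixed
365-day window (one person-year for every patient, guaranteed by the
enrollment criterion) is algebraically the weighted rate ratio. Both
identities are enforced as tests at `1e-10` and `1e-8` — the regression
route is kept because it generalizes, the closed form because it cannot be
wrong.

Confidence intervals and p-values come from a nonparametric bootstrap
(default 499 replications) that resamples patients with replacement within
each treatment cohort, preserving cohort sizes, and by default re-estimates
the propensity model and weights in every replicate so that weighting
uncertainty propagates. The 95% interval is the 2.5/97.5 percentile
interval; the two-sided p-value is the percentile inversion
`2·min(#{θ* ≤ θ₀}, #{θ* ≥ θ₀})/B` with `θ₀ = 0` for cost differences and
`log θ* ≤ 0` for rate ratios. Replicates in which an estimator fails
(e.g., an empty weighted cell) are dropped; more than 5% failures aborts
inference. All estimands share one set of replicates inside
`run_outcome_suite()`, which is both faster and statistically coherent.
No multiplicity adjustment is applied anywhere.

## The synthetic generator and what it does (not) show

The generator's defaults are the package's study conditions and are not
tuned per run. Covariates (age, sex, race, state, region, eligibility
flags, comorbidity flags, baseline admission counts, prior antipsychotic
use) feed a logistic treatment-assignment model, so confounding operates
only through covariates the propensity model observes and IPTW estimates
are consistent by construction; an unmeasured confounder would have to be
added deliberately by extending the assignment design. Index fills follow
a renewal process: 30-day supplies separated by geometric extra gaps whose
mean (10 days treated, 16 comparator, log-normally scaled by a patient
adherence latent) controls the implied PDC — absent discontinuation the
long-run PDC is `supply/(supply + mean gap)` — with a per-fill
discontinuation hazard and a truncated first gap so the two-claims-in-90-days
rule holds by construction. Monthly medical cost is gamma with a zero
point mass (8%), mean equal to a covariate term plus an additive treatment
effect of −300 USD/month; utilization counts are Poisson with a
multiplicative treatment rate ratio of 0.84 on every category. The
materialized bundle writes follow-up claim amounts in service-year dollars
such that CPI standardization recovers the drawn cost exactly, and drops
claims inside configured enrollment holes so strict validation passes.

Monte-Carlo studies use the patient-level path
(`simulate_analysis_sample()`), which skips claims materialization; the
full claims path (`generate_bundle()`) is exercised end-to-end at smaller
sizes. Simulation sizes were chosen once as the package's study design:
balance is assessed over 100 seeds at n = 4000; parameter recovery over
200 repetitions at n = 3000; bootstrap calibration at B = 199 over 200
repetitions of n = 1000 (coverage of a percentile interval is a
large-sample property, and n = 1000 is comfortably in its regime while
keeping the study a few minutes long). The treated share is ≈ 35% rather
than the single-digit share seen in real data, because desk-scale
simulations need both arms populated.

What passing these simulations does **not** show: robustness to unmeasured
confounding, to outcome models whose cost effect is not additive on the
mean, to misclassified agent dictionaries, or to the messy enrollment and
billing patterns of real Medicaid extracts (retroactive eligibility,
capitation encounters with zero paid amounts, transfers between states).
The generator emulates the statistical structure the estimators assume, not
the administrative pathology of real claims.

## Degenerate inputs and numerical conventions

Empty claim tables validate and flow through every stage; a patient with no
fills has PDC 0, no continuous exposure and (under the default
terminal-gap mode) no persistence. A pooled prevalence of exactly 0 or 1
makes the binary standardized difference undefined; it is returned as 0
with a warning. Two arms with zero pooled variance and unequal means raise
an error rather than return infinity. Propensity designs drop empty
categorical levels, and a genuinely rank-deficient design is an error
naming the collinear columns rather than a silent aliasing: the
total-cost column is excluded from the default design because it is the
exact sum of the pharmacy and medical columns. The rate-ratio estimator
refuses a zero comparator event total (the ratio is undefined) and returns
0 for a zero treated total without fitting.

## Reproducibility

Every stochastic stage takes a seed; the pipeline derives per-stage
substreams from one master seed, records it in every artifact, and rerunning
a configuration reproduces all numeric outputs exactly. Bundles round-trip
through their delimited-text form field-for-field, so a written bundle is a
complete, portable record of a simulated study.
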