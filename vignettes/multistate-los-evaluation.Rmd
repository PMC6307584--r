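---
title: "Evaluating an in-stay intervention: multistate length-of-stay methods in bedrelease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating an in-stay intervention: multistate length-of-stay methods in bedrelease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bedrelease)
```

## The problem

An intervention delivered *during* a hospital stay — here, a specialist
social-worker model of care targeting patients at risk of long stays —
cannot be evaluated by comparing the mean length of stay (LOS) of patients
who did and did not receive it. Receipt of the intervention is conditional
on still being in hospital, so treated patients are selected for long stays
(immortal-time bias). The standard remedy treats the intervention as an
**intermediate state** of a multistate model and asks, at each time a
patient entered that state, how the expected remaining stay differs between
a patient who has and has not entered it.

## The model and the estimand

Patients start at admission (time 0) in state 0 (in hospital,
pre-intervention), may move to state 1 (in hospital, post-intervention), and
are absorbed at discharge (state 2). No backward transitions occur. From a
table of transition counts `d01, d02, d12` and risk sets `y0, y1` at the
distinct event times, the Aalen–Johansen estimator gives the transition
probability matrices as finite products of increment matrices,

$$\hat P(s, t) = \prod_{u \in (s, t]} \big(I + d\hat A(u)\big),$$

with empirical-hazard increments `d01/y0`, `d02/y0`, `d12/y1`
(`aalen_johansen()`). The expected LOS given the state occupied at `s`
integrates the in-hospital probability as a right-continuous step function,

$$\hat e_j(s) = s + \sum_k (u_{k+1} - u_k)\,
\big[\hat P_{j0}(s, u_k) + \hat P_{j1}(s, u_k)\big],$$

(`expected_los_given_state()`), and the change-in-LOS estimand is the
weighted average over intermediate-event times

$$\hat\Delta = \sum_s \big(\hat e_1(s) - \hat e_0(s)\big)\, w(s), \qquad
w(s) = \frac{\Delta \hat F_1(s)}{\hat F_1(\tau)},$$

where $\hat F_1(s) = \sum_{u \le s} \hat P_{00}(0, u^-)\, d\hat A_{01}(u)$
is the cumulative probability of experiencing the intermediate event
(`estimate_clos()`). A negative $\hat\Delta$ means the intervention is
associated with shorter stays; *bed days released per patient* is
$-\hat\Delta$. This weighting is the standard form for excess-LOS
estimation in illness-death models; it concentrates on times where entries
into the intermediate state actually occurred and is the one methodological
reconstruction in the package, since applied reports rarely restate it.

Uncertainty comes from a nonparametric bootstrap that resamples whole
patients with replacement and recomputes $\hat\Delta$ (percentile intervals,
default B = 1000). We chose unstratified resampling from the pooled sample
as the default — the literal reading of "bootstrapping the data" in applied
practice — with cohort-stratified resampling as an option. Percentile rather
than BCa intervals are used because the estimand's applied literature
reports none of the refinements; replicates whose resample contains no
intermediate events or no discharges are dropped and counted (`n_failed`),
and more than 50% failures abort with advice rather than returning a CI
built on a selected minority.

## Numerical and convention choices

* **Horizon.** Integration is truncated at $\tau$, the largest observed
  event time; in-hospital probability beyond $\tau$ is treated as zero.
  This is the usual practical choice and makes $\hat e_j(s)$ finite without
  extrapolating the tail.
* **Ties.** Day-granular administrative data makes tied times common. At a
  tied time the conventions are: 0→1 entries before 1→2 exits, transitions
  before censorings. A patient intervened and discharged on the same day
  receives an infinitesimal state-1 sojourn: the increment matrix at that
  time factorises into a state-0 stage followed by a state-1 stage whose
  risk set includes same-time entrants, so no hazard is ever 0/0. With all
  event times distinct, this reduces exactly to the classical
  Aalen–Johansen increment.
* **Degenerate inputs.** A cohort with no intermediate events, or no
  discharges, has no estimand support; `estimate_clos()` raises a classed
  error instead of silently returning a difference of naive means. Empty
  risk sets inside the product contribute identity increments.
* **Efficiency.** `estimate_clos()` evaluates $\hat e_j(s)$ at all
  intermediate-event times with one backward recursion over the event grid
  (linear in the number of event times) rather than one product integral
  per `s`; the explicit `aalen_johansen()` route is retained and the test
  suite checks the two agree to 1e-9, alongside exact comparisons with
  hand-computed products on cohorts of up to four patients.
* **Time origin.** Admission is day 0 for both cohorts, with no left
  truncation; controls, who can never enter state 1, contribute
  direct-discharge transitions to the pooled risk set. A `cohorts` filter
  supports intervention-era-only analyses.

## The economic model

`run_monte_carlo()` converts the bootstrap draws of bed days released per
patient into decision quantities over a 12-month horizon. Each of `n_sims`
(default 1000) simulations independently draws `b` (bed days per patient,
resampled from the supplied draws) and `m` (patients managed per month,
continuous uniform on [20, 30] by default; a discrete-uniform option
exists), then computes annual bed days `b·m·months` and cost per bed day
`total_cost / (b·m·months)`. Defaults reflect the emulated evaluation: team
cost components of $158,000 and $71,000 per year (sum $229,000) with an
exact total of $228,876 used in the cost arithmetic — both figures are
reported because rounded components and exact totals commonly coexist in
published costings and the per-bed-day arithmetic should reproduce the
exact one — and a willingness to pay (WTP) of $216 per bed day released,
taken from a survey of hospital chief executives and exposed as a plain
threshold parameter. Simulations with `b ≤ 0` release no bed days: their
cost per day is undefined, they are excluded from cost summaries, and they
count as *not* meeting the WTP criterion — the conservative direction for a
decision maker. `ceac()` sweeps the threshold over a grid to give the
cost-effectiveness acceptability curve, which is non-decreasing by
construction. Pairing of `b` and `m` is independent resampling by default;
a one-to-one mode consumes the bootstrap replicates in order when
`n_sims` equals their number, since published summaries do not always
reveal which scheme was used. Costs are not discounted (the horizon is one
year) and no health outcomes are valued: this is a cost-per-bed-day
analysis, not a full cost-effectiveness analysis.

## What the synthetic generators emulate

Real patient-level records for this kind of evaluation are rarely
deposited, so the package ships two generators.

`simulate_markov_cohort()` draws from the time-homogeneous Markov version
of the three-state model (exponential competing sojourns). Its value is the
closed form of the estimand: with intensities $\alpha_{01}, \alpha_{02},
\alpha_{12}$,

$$\phi = \frac{1}{\alpha_{12}} - \left[\frac{1}{\alpha_{01}+\alpha_{02}}
 + \frac{\alpha_{01}}{(\alpha_{01}+\alpha_{02})\,\alpha_{12}}\right],$$

constant in `s`, hence equal to any weighted average of $\phi(s)$
(`closed_form_clos()`). This gives exact parameter-recovery tests: at
$(0.02, 0.01, 0.05)$/day the truth is $-26.67$ days, and
$\alpha_{02} = \alpha_{12}$ gives exactly zero.

`simulate_study_cohort()` emulates a published two-cohort evaluation: 52
intervention-era patients following the Markov dynamics and 60 historical
controls discharged at a single constant hazard, with Table-1-style
demographics (ages normal with mean 69, SD 18 in controls and mean 74,
SD 14 in the intervention era; 23 female patients in each cohort). The
default hazards were calibrated once, by coarse grid search, to the
published marginal summaries: an exponential time to intervention with
median 25 days has quartiles 10.4 and 50 days, closely matching the
reported IQR of 9–50, fixing $\alpha_{01}+\alpha_{02} = \log 2/25$; we set
the intervened fraction to 0.9 (most eligible patients are reached) and the
remaining discharge hazards ($\alpha_{12} = 0.0348$, control $0.013$) so
the pooled mean LOS is 70 days in expectation. Simulated cohorts are
checked against the scenario's implied summaries (tolerance ±10 days on
both the mean LOS and the median time to intervention, config-exposed) and
fail with a calibration error naming the violated summary rather than
returning an unrepresentative sample. Censoring defaults to none — the
emulated study reports completed stays up to 422 days — but a `censor_time`
option exercises the estimator under censoring.

These generators reproduce the *statistical structure the estimator
assumes*: exponential sojourns, independent censoring, admission as the
common time origin. They deliberately do not reproduce features of the real
data-generating process that the original design could not address either:
historical controls selected on having already met a long-stay definition
(a selection bias the published study acknowledges), the 11 psychosocial
risk factors driving referral, or non-Markov dependence of discharge
hazards on time since intervention. Passing tests on synthetic cohorts
therefore validate the estimator and pipeline, not the causal
interpretation of any particular real-world result. The study's published
headline numbers (33 bed days released per patient, 9999 annual bed days,
the 5–70 bootstrap range, 82% below $100) depend on its undeposited cohort
and are not reproduction targets; the package's validation rests on the
closed-form oracle, the Kaplan–Meier reduction, and arithmetic checks
computable from stated distributions.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `B` (bootstrap) | 1000 | replicates | conventional for percentile CIs; matches the emulated analysis |
| `level` | 0.95 | — | conventional |
| `n_sims` | 1000 | simulations | matches the emulated probabilistic analysis |
| `patients_per_month` | U(20, 30) | patients | reported activity range of the team |
| `total_cost_override` | 228,876 | AUD/year | exact published total; components sum to 229,000 |
| `wtp` | 216 | AUD/bed day | surveyed decision-maker willingness to pay |
| `tau` | max event time | days | truncation horizon of the estimator |
| study hazards | 0.02495, 0.00278, 0.0348; control 0.013 | /day | one-off calibration to mean LOS 70 d, median time-to-intervention 25 d |

## Validation problem sizes

The test suite recovers the closed form at $n = 5000$ patients within three
bootstrap standard errors, verifies the null case
($\alpha_{02}=\alpha_{12}$) at the same size, checks exact equality of
$\hat P_{00}(0,\cdot)$ with the Kaplan–Meier estimator when no intermediate
events exist, and runs a coverage study of the percentile interval (50
independent cohorts of 5000, B = 200, requiring ≥ 90% coverage of the
closed-form value). Property tests on randomly generated small cohorts —
with integer-day ties and censoring — assert row-stochasticity, monotone
absorption, agreement with brute-force product integrals, and conservation
identities of the economic model. These sizes were chosen so Monte Carlo
error is well below the effects being checked while the whole suite runs in
a couple of minutes.

## Known limitations

* No covariate adjustment or Cox-type transition models; the estimand is a
  marginal association, and confounding by indication is out of scope.
* The ΔF1 weighting is a reconstruction of standard excess-LOS practice
  (see above); alternative weightings (e.g. by number of entries rather
  than estimated probability increments) would differ in small samples.
* Percentile intervals can undercover for strongly skewed replicate
  distributions at small `n`.
* The economic model treats costs as certain and values no health outcomes.
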