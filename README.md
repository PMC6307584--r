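# bedrelease

Hospitals evaluating an in-stay intervention — here, a specialist
social-worker-led model of care for patients at risk of a long stay — need an
estimate of how many bed days the intervention releases and what each
released bed day costs. Comparing the mean length of stay (LOS) of treated
and untreated patients is biased, because patients must survive in hospital
long enough to receive the intervention. `bedrelease` implements the standard
multistate solution for analysts and health economists working with
patient-level admission data:

* **Three-state multistate model.** Patients move from state 0 (in hospital,
  pre-intervention) either directly to discharge (state 2) or via the
  intervention (state 1). Transition probabilities `P_jk(s, t)` are estimated
  with the Aalen–Johansen product-integral estimator, which handles
  censoring and ties.
* **Change-in-LOS estimand.** For each observed intervention time `s`,
  `phi(s) = e_1(s) − e_0(s)` contrasts the expected LOS of a patient in
  state 1 at `s` with one still in state 0 at `s`, where
  `e_j(s) = s + ∫ [P_j0(s,u) + P_j1(s,u)] du` up to the horizon `tau`. The
  estimate `delta = Σ phi(s) w(s)` weights each time by the increment of
  `F1(s)`, the cumulative probability of experiencing the intervention.
  Bed days released per patient = `−delta`.
* **Patient-level bootstrap.** Percentile confidence intervals from
  resampling whole patients with replacement (default B = 1000).
* **Monte Carlo economic model.** Draws bed days released per patient from
  the bootstrap distribution and patients managed per month from a uniform
  distribution, yielding annual bed days released, cost per bed day
  released, the probability of beating a willingness-to-pay (WTP) threshold,
  and a cost-effectiveness acceptability curve (CEAC).
* **Synthetic cohorts.** A time-homogeneous Markov generator with a
  closed-form value of the estimand (`closed_form_clos()`) for validation,
  and a study-like generator emulating a published two-cohort evaluation
  (52 intervention-era patients, 60 historical controls, pooled mean LOS
  ≈ 70 days).

Everything takes and returns tibbles; fitted objects support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

```r
library(bedrelease)

records <- simulate_study_cohort(study_scenario(seed = 1))
fit <- estimate_clos(records)
fit
#> Change in expected length of stay (three-state multistate model)
#>   delta: -36.07 days (36.07 bed days released per patient)
#>   112 patients, 46 intermediate-event times, horizon tau = 219.9 days

boot <- bootstrap_clos(records, B = 1000, seed = 1)
boot
#> Bootstrap of the change in expected length of stay
#>   point estimate: -36.07 days (36.07 bed days released per patient)
#>   95% percentile CI: (-46.77, -25.16) days
#>   B = 1000 replicates (0 failed), seed 1

sim <- run_monte_carlo(boot$bed_days_released, econ_config(seed = 2))
tidy(sim, rounded = TRUE)
#> # A tibble: 4 × 5
#>   quantity              mean    sd   min   max
#> 1 bed_days_per_patient    36     5    17    53
#> 2 patients_per_month      25     3    20    30
#> 3 annual_bed_days      10821  2112  4810 19003
#> 4 cost_per_bed_day        22     5    12    48
```

The intervention in this simulated cohort is associated with a stay
shortened by 36 days on average (95% CI 25 to 47 bed days released per
patient). At the default team cost of $228,876 per year and 20–30 patients
managed per month, a released bed day costs about $22, and every one of the
1000 simulations beats a $216 willingness to pay (`sim$p_meets_wtp` is 1), so
`ceac(sim)` is flat at 1 from well below that threshold.

`run_pipeline(run_config(records = records, output_dir = "out", seed = 1))`
runs all stages (demographics, estimate, bootstrap, economic model) and
writes CSV/JSON outputs plus a manifest with the seed and config hash; a
command-line wrapper with `simulate | estimate | bootstrap | econ | all`
subcommands lives at `inst/scripts/los-pipeline.R`.

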