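# wearversion

Physical-activity research increasingly relies on participant-owned
smartwatches, but the daily summaries those devices report (exercise
minutes, active calories) are produced by undisclosed algorithms that
change with every annual software release and every hardware generation. A
study that spans upgrades can therefore confuse a change in *measurement*
with a change in *behaviour*. `wearversion` implements a within-person
pre/post design for quantifying that measurement effect from routinely
collected HealthKit-style data, for epidemiologists and measurement
researchers working with wearable cohorts.

The pipeline:

1. **Wear time** — gaps of ≥ 40 minutes between heart-rate samples are
   non-wear segments (the optical sensor samples every few minutes while
   worn); a day with ≥ 600 wear minutes is a valid wear day.
2. **Person-day filters** — sex-specific 99.9th-percentile outcome
   outliers and low-wear days are excluded.
3. **Versions** — each day gets the modal major software version and
   hardware generation of its heart-rate metadata (`"7.3.1"` → 7;
   `"Watch6,2"` → `Series 6` via a bundled editable index).
4. **Transitions** — the transition date is the first day on which a
   strict majority of measurements carry the new version; 14-day treatment
   (offsets −7..+6) and control (−14..−1) windows are built under the
   eligibility rules (consecutive software versions only, no other version
   change in the window, activity in both weeks).
5. **Estimation** — person-level pre/post change summaries, and
   mixed-effects negative binomial regression per transition:

   log μ_ij = β₀ + β₁·post_ij + γ′·weekday_ij + b_i,  b_i ~ N(0, σ_b²),
   Var(y|b) = μ + αμ² (NB2),

   fitted by maximising the marginal likelihood with the random intercept
   integrated out by adaptive Gauss–Hermite quadrature; the rate ratio is
   RR = exp(β₁) with a 95% Wald CI on the log scale.

A synthetic-cohort generator with a ground-truth ledger (upgrade instants,
true multiplicative effects) makes every stage testable without any
external data, and a deterministic seven-participant toy fixture exercises
every rule in a hand-checkable place.

## Worked example

```r
library(wearversion)

toy  <- generate_worked_toy()
wear <- estimate_daily_wear(toy$heart_rate, toy$activity)
thr  <- percentile_thresholds(toy$activity, toy$participants)
filt <- apply_exclusions(toy$activity, wear, thr, toy$participants)
dv   <- assign_day_versions(toy$heart_rate)
ev   <- rbind(
  detect_transitions(count_day_versions(toy$heart_rate, "software"), "software"),
  detect_transitions(count_day_versions(toy$heart_rate, "hardware"), "hardware"))
ev    <- assess_eligibility(ev, dv, filt$activity)
panel <- build_panels(ev, filt$activity, toy$participants)
fit_nb_glmm(panel[panel$label == "watchOS 7 to 8", ])
#> NB mixed model (watchOS 7 to 8, treatment, exercise_minutes, overall)
#>   RR = 1.000 (95% CI 0.852, 1.173)
#>   alpha = 0.000, sigma_b = 0.002, logLik = -39.88, n = 1 participants / 14 days
```

The toy's one eligible software upgrader has a flat deterministic activity
pattern, so the fitted rate ratio is 1.00: the upgrade changed nothing,
and the model says so. On simulated cohorts with a known injected effect
the estimator recovers it:

```r
set.seed(2024)
rec <- recover_rr(true_rr = 1.13, n_participants = 166, n_replicates = 20)
mean(rec$rr)
#> [1] 1.128
```

`run_full_analysis()` drives the whole grid (5 transition labels ×
treatment/control × overall/female/male × unadjusted/weekday-adjusted ×
both outcomes, plus completeness sensitivity reruns), and
`cmd_simulate()` / `cmd_analyze()` / `cmd_recover()` (or the
`exec/wearversion` script) expose it from the shell.

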