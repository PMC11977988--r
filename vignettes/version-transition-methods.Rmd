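---
title: "Estimating version-upgrade effects on wearable activity metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating version-upgrade effects on wearable activity metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Consumer smartwatches summarise daily physical activity (exercise minutes,
active calories) with undisclosed, vendor-controlled algorithms. Those
algorithms change with every annual major software release and with each
hardware generation, so two otherwise identical days recorded under
different versions need not produce the same numbers. For longitudinal
research built on participant-owned devices this is a measurement-error and
confounding problem: an apparent activity trend can be an artefact of the
device population silently upgrading underneath the study.

`wearversion` implements a within-person pre/post design for quantifying
this effect. Each participant's own upgrade provides the comparison: the
seven days before the switch versus the seven days from the switch onward.
Because no outcome data identify the switch directly, the pipeline
reconstructs it from metadata stamped on minute-level heart-rate records —
the raw software version string (e.g. `"7.3.1"`) and the hardware product
identifier (e.g. `"Watch6,2"`) of the recording device.

## Pipeline stages and their rules

**Wear time.** The optical heart-rate sensor only samples while the watch
is worn (every 5–6 minutes on average), so sampling gaps proxy non-wear.
Any interval of 40 minutes or longer without a measurement is a non-wear
segment; the threshold is inclusive (a gap of exactly 40.0 minutes counts),
because the off-by-one at the boundary is the classic defect in gap-based
algorithms and the rule is stated as "40 minutes or longer". Segments are
split at midnight so that each calendar day conserves exactly 1440 minutes
of wear + non-wear, and the first/last days of a participant's range use
the range boundaries as virtual measurements (a late first measurement
produces a leading gap — the conservative choice). A day with at least 600
wear minutes is a valid wear day; exactly 600 is valid ("under 600" is
excluded).

**Person-day filters.** Within each sex, person-days at or above the
99.9th percentile of either outcome are dropped as device artefacts, using
the linear-interpolation quantile (type 7) — implementations differ enough
at extreme tails that the definition is fixed and documented. Thresholds
are computed once over each sex's full pre-filter history: pooling within
sex is the only reading that gives the 0.1% tail usable resolution, and
computing them before the wear filter keeps the threshold independent of
wear-estimation choices. Days with under 600 wear minutes, or without any
wear record, are also dropped.

**Day-level versions.** The software version of a day is the mode of the
major versions (integer before the first dot) over that day's heart-rate
measurements; hardware identifiers are first mapped to marketing
generations via a bundled editable index so size/cellular variants merge.
Ties break toward the newer version — numerically for software, by
later-first-appearance for hardware (generations are not totally ordered
across product lines). Rationale: upgrades are monotone in time, so on the
cusp day the new version is operative.

**Transition dates.** The transition date is the first day on which
*strictly more than half* of the day's measurements carry the new version.
"Most" is read as a majority, and strictness prevents a 50/50 day from
qualifying. The 14-day treatment window spans offsets −7..+6 around that
date, the transition date opening the post week. The control window spans
offsets −14..−1, its two 7-day halves compared the same way; since no
version changes inside it, it estimates normal week-to-week variability.
(The equal-weeks −14..−8 / −7..−1 geometry is used; a 15-day reading of the
control period would break the stated 14-day design.)

**Eligibility.** Software events are analysed only for consecutive major
upgrades (5→6 … 8→9) and are excluded when the major version changes more
than once in the window, when hardware changes at any point in the window,
or when either week has no surviving activity day. Hardware events are the
mirror image: any software change in the window excludes, the pre-week must
be entirely on the old device and the post-week entirely on the new one,
and both weeks need activity. Reasons accumulate rather than
short-circuiting, so exclusion accounting is complete. Eligibility is
evaluated on activity *after* the person-day filters — a week of
all-invalid days counts as empty; the ordering of filters versus
eligibility is fixed here because it is otherwise ambiguous.

**Completeness.** The primary analysis requires activity on all 14 window
days; sensitivity settings require at least 1, 4, 5 or 6 days per
half-window. Each participant contributes at most one window per transition
label, so a single random intercept per participant is well defined.

## The model

Daily outcomes are counts with strong between-person heterogeneity and
within-person overdispersion, so the effect of a transition is estimated by
a mixed-effects negative binomial regression:

$$y_{ij} \mid b_i \sim \mathrm{NB2}(\mu_{ij}, \alpha), \qquad
\log \mu_{ij} = \beta_0 + \beta_1 \, \mathrm{post}_{ij}
  + \boldsymbol{\gamma}' \mathrm{weekday}_{ij} + b_i, \qquad
b_i \sim N(0, \sigma_b^2),$$

with $\mathrm{Var}(y \mid b) = \mu + \alpha \mu^2$ (NB2 — the standard
epidemiological parameterisation, matching rate-ratio reporting) and a log
link. The rate ratio is $RR = e^{\beta_1}$ with a 95% Wald interval on the
log scale. Weekday adjustment uses six indicator contrasts with the panel's
modal transition weekday as reference, making $\beta_1$ interpretable at
the weekday upgrades typically happen on. Outcomes are rounded to integers
for the count likelihood (calories are large counts; rounding error is
negligible). Dispersion is estimated per model, not shared across strata.

The marginal likelihood integrates the random intercept out by *adaptive*
Gauss–Hermite quadrature (default 11 nodes; estimates are stable from 9
up — a built-in check verifies the RR moves by less than $10^{-3}$ between
9 and 15 nodes). Per participant, the integrand's mode is found by damped
Newton iteration (the NB log-link likelihood is strictly concave in the
intercept), and the node grid is centred and scaled at the mode.
Optimisation is quasi-Newton (PORT) on $(\beta, \log \alpha, \log
\sigma_b)$ with relative tolerance $10^{-6}$, starting from a Poisson GLM
for $\beta$, $\alpha = 1$, $\sigma_b = 0.5$. $\log \sigma_b$ is bounded
below at −7 so fits degrade gracefully to a plain NB regression when the
data carry no between-person variance; `sigma_fixed = 0` pins it there
exactly, and tests verify coefficient agreement with `MASS::glm.nb` to
$10^{-3}$ in that limit and agreement with `glmmTMB`'s Laplace fit on
heterogeneous data. When a fit does not converge, no confidence interval is
reported.

## The synthetic cohort and what it does (not) show

No raw cohort of this kind is publicly deposited, so validation is by
parameter recovery on a generator that emulates the data-generating
process: NB2 daily counts with participant random intercepts, a
multiplicative weekday pattern, sex-specific baselines, annual software
releases adopted 25–31 days after release, heart-rate inter-sample times
that are exponential with mean 5.62 minutes truncated at 1 minute, daily
non-wear blocks, missing activity days, and a small fraction of
device-alternating participants. The version switch happens at a uniform
instant within the adoption day, so the switch day's records are split
between versions and transition-date detection is genuinely exercised; the
ground-truth transition date follows the noon rule (a switch before 12:00
makes that day the majority-new day, later switches push it to the next
day), which matches the strict-majority estimand up to sampling noise.

Effects enter multiplicatively on the mean and switch *exactly* at the
transition date — the identifying assumption of the pre/post design, and
what makes recovery tests well-posed. Real upgrades need not behave this
way (novelty effects, partial-day rollouts, behavioural responses to new
features), so passing recovery says the *pipeline and estimator* are
correct, not that the design is immune to behavioural confounding.
Seasonality and novelty add-ons are deliberately absent from the defaults.

Two generator parameters are not directly observable and were calibrated
once from published summary quantities of this design, before any test was
run, and not revisited:

* **Dispersion $\alpha$** from the Wald CI widths of the fitted rate
  ratios: for a within-person pre/post contrast,
  $\mathrm{SE}(\log RR)^2 \approx 2(\alpha + 1/\mu)/(7n)$, giving
  $\alpha \approx 0.45$ for exercise minutes and $\approx 0.08$ for active
  calories.
* **Random-intercept SD $\sigma_b$** from the spread of participant
  pre-week means: the variance of a 7-day average is
  $\mu^2(e^{\sigma_b^2}-1) + (\mu + \alpha\mu^2 e^{\sigma_b^2})/7$, giving
  $\sigma_b \approx 0.57$ (exercise) and $\approx 0.33$ (calories) at the
  observed baselines (mean 48.97, SD 34.05 for exercise; 710.43, SD 250.62
  for calories).

With `hr_coverage = "windows"` (the default) heart-rate streams are
emitted only within a ±buffer of each upgrade — the only days any pipeline
stage consumes — so the default 250-participant, four-year cohort stays
desk-sized (~6 million records); `"full"` coverage is available for small
cohorts. Problem sizes used throughout the validation suite: 200 replicate
panels per recovery condition at the study's panel sizes (97–166
participants × 14 days), and one 250-participant cohort for end-to-end
ground-truth recovery.

`generate_worked_toy()` is the deterministic counterpart: seven
hand-constructed participants in which every rule — the inclusive
40-minute gap, the exactly-600-minute valid day, the non-qualifying 50/50
day, each eligibility exclusion reason, the same-generation identifier
merge — fires in a known place. Note one unavoidable geometry fact the toy
documents: two version changes at most six days apart each lie inside the
other's 14-day window, so the "changed more than once" reasons necessarily
appear on both events of their designed case.

A worked run:

```{r}
library(wearversion)
toy <- generate_worked_toy()
wear <- estimate_daily_wear(toy$heart_rate, toy$activity)
thr <- percentile_thresholds(toy$activity, toy$participants)
filt <- apply_exclusions(toy$activity, wear, thr, toy$participants)
dv <- assign_day_versions(toy$heart_rate)
ev <- rbind(
  detect_transitions(count_day_versions(toy$heart_rate, "software"), "software"),
  detect_transitions(count_day_versions(toy$heart_rate, "hardware"), "hardware"))
ev <- assess_eligibility(ev, dv, filt$activity)
panel <- build_panels(ev, filt$activity, toy$participants)
fit_nb_glmm(panel[panel$label == "watchOS 7 to 8", ])
```

## Numerical and degenerate-input choices

* Timestamps are timezone-naive local instants; days are the user's local
  calendar days. Exact duplicate heart-rate rows (paired devices reporting
  the same sample) are dropped; how real paired-device duplicates should
  merge is unknowable from the data, so dedup-on-exact-match plus the
  transition module's exclusion rules is the policy.
* A covered date with no measurements is a whole non-wear day (wear 0,
  invalid), not a missing day; a date with neither heart-rate nor activity
  records is missing.
* A day whose records are all unknown hardware identifiers has no hardware
  assignment and is skipped by hardware eligibility scans.
* Unparseable version strings and unknown identifiers are counted and
  logged, never silently dropped.
* All-zero outcomes and empty strata are hard errors at the fit level and
  reported, non-fatal cells at the pipeline level.

## Limitations

Single random intercepts only (no random slopes, GEE, or small-sample
corrections); effects of specific hardware generations are not separable
from pooled hardware changes; joint software+hardware upgrades are not
modelled; the generator's independence of the two outcomes' random
intercepts is a simplification; and the confidence-interval method (Wald on
the log scale) and NB2 parameterisation are documented package choices —
other implementations of this design may differ at the margins.
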