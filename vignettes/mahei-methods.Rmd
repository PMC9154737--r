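---
title: "Methods: m-AHEI scoring, advice, QC and treatment-effect estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: m-AHEI scoring, advice, QC and treatment-effect estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maheitrial)
```

This vignette documents the models and procedures the package implements,
the assumptions behind them, and the design decisions taken where the
underlying study protocol leaves the choice open.

## The diet-quality model

The m-AHEI scores 11 food and drink components, each on 0–100, against a
declarative criterion: an intake at which the score is 0 and an intake at
which it is 100, with pure linear interpolation between them and clamping
outside. Healthy components (vegetables, fruit, whole grains, dairy, nuts
and legumes, healthy fats, oily fish) have a positive slope; unhealthy
components (free sugars, red and processed meat, salt, alcohol) a negative
one, so a higher score always means better diet quality. The overall score
is the *equally weighted* arithmetic mean of the 11 components, presented
as a 0–100 percentage; the AHEI-family 0–110 pre-scaling sum (11
components × 10 points) is exposed via `to_scale110()` because effect
sizes are quoted on both scales (a 3.5-point effect out of 100 is 3.85 ≈
3.9 out of 110).

**Assumptions.** Scoring is memoryless and unit-agnostic: every amount is
an opaque scalar in the criterion's declared metric (servings/day, g/day,
%energy, drinks/day); unit conversion is the data producer's job. No
component is scored non-monotonically — alcohol, which some indices score
with a moderate-intake optimum, is treated as linearly decreasing here,
consistent with a pure interpolation engine.

**Criteria provenance.** The deployed decision engine's exact cutpoints
live in a supplementary criteria table that is not reproduced here. The
packaged default (`mahei_criteria()`, also shipped as
`inst/extdata/mahei_criteria.json`) is a clearly labelled stand-in adapted
from the AHEI-2010 with UK-guideline units (e.g. 5 vegetable servings/day,
90 g/day whole grains, salt full score at ≤ 6 g/day). All scoring,
advice, and simulation logic is criteria-agnostic: replace the table via
`read_criteria()` and everything downstream follows it.

## The advice engine

Advice targets the **3 lowest-scoring components**. Ties are broken by the
fixed criteria order (the row order of the criteria table), which makes
the selection deterministic and invariant to how scores happen to be
stored; `select_advice_components(k = 11)` is consistent with `k = 3` by
construction. Each message carries up to 3 top contributing foods from the
participant's own FFQ, ranked by contribution with ties broken by
ascending `food_id`; the message prose is template-driven configuration,
not algorithm.

**BMI feedback.** The healthy range is 18.5–25.0 kg/m²; the ideal weight
shown is the weight at the midpoint BMI, 21.75 kg/m². "Distance to the
ideal BMI" is ambiguous between distance to that midpoint and distance to
the nearest bound of the range. Both are computed
(`distance_to_midpoint`, `distance_to_range`); the midpoint convention is
primary, because the midpoint is explicitly presented as *the* ideal BMI,
and the secondary-outcome analysis (`bmi_outcomes()`) uses it.

**Baecke physical activity.** Work, sports and leisure indices are built
from items on 1–5 scales and rescaled linearly so the instrument minimum
maps to 0 and the maximum to 100 ((index − 1)/4 × 100) — the minimal
assumption consistent with a published 0–100 presentation. Answers are
expected pre-coded so that higher = more active (reversing
negatively-worded items is a data-entry convention); with that coding the
category index is the item mean, minimum answers give 0, maxima give 100
and midpoints give 50. The full sport-intensity composite of the original
instrument is out of scope. No advice message is attached to the work
category — participants rarely control their activity at work. Low /
moderate / high message variants split at 40 and 70 points by default
(configurable; the deployed thresholds are not published).

**Control reports** are participant-independent: vegetables, free sugars
and healthy (polyunsaturated) fats at baseline; fruit, whole grains and
red or processed meat at week 6. Where a week-6 personalized report is
generated, components are re-selected from the week-6 FFQ rather than
frozen at baseline, matching a progress-report design.

## Quality control

Filters, applied to the two analysed FFQs per participant (baseline and
endpoint):

| Rule | Default | Notes |
|---|---|---|
| EI/BMR plausibility | men kept in [0.49, 2.79]; women [0.56, 3.21] | strict inequalities exclude; BMR from the Henry weight-only equations |
| Energy discrepancy | exclude if \|ΔEI\| > 8000 kJ and \|Δweight\| < 1 kg | 1 kg = self-report noise floor; threshold configurable |
| Feasibility | per-food-group maxima | defaults strictly below published offending examples (eggs 9/day, porridge 1100 g/day); stand-ins for survey-derived limits |
| Endpoint selection | post-baseline completion closest to day 84; ties → later visit | baseline is never the endpoint |

Decisions taken where the protocol is silent: EI/BMR is evaluated on
*both* analysed FFQs and excludes if either fails (the conservative
reading; switchable to baseline-only); a missing endpoint weight leaves
the discrepancy rule unevaluable, so the participant is retained and
flagged (switchable to exclude). The Henry coefficients (MJ/day, sex ×
age-band, weight-only) ship as an editable CSV. Verdicts are the
conjunction of the individual filters — reasons accumulate, so filter
order affects nothing but the accounting table, whose percentages round
half-up to one decimal (`round_half_up()`; base R's banker's rounding
would disagree with printed trial tables at exact halves).

FFQ availability gates (second questionnaire from day 41, third from day
83) and 24-hour expiry of incomplete questionnaires are modelled in
`ffq_available()` and the simulator's visit schedule.

## Treatment-effect estimation

The estimator is a change-score ANCOVA: for each outcome,

  change ~ group + covariate,

with the group coefficient (intervention − control) as the treatment
effect, model-based two-sided 95% t-intervals, and p-values from the same
fit; 0.05 is the declared significance threshold. Diet-quality outcomes
(overall and components) use baseline energy intake as the covariate — it
absorbs the systematic drop in reported energy at follow-up; secondary
outcomes (BMI, activity) use their own baseline value. Adjusted per-arm
changes are model predictions at the grand covariate mean; their reported
SDs are within-arm residual SDs. The alternative endpoint-on-baseline
formulation is deliberately not the default: the change-score form matches
the declared analysis, and with randomized arms both are unbiased.

Transforms are *declared per outcome*, not chosen by automatic tests: the
three right-skewed components (whole grains, nuts and legumes, red and
processed meat) are square-root transformed by default, applied to the
score values before forming changes. Normality checking
(`normality_check()`: Shapiro–Wilk plus a D'Agostino–Pearson omnibus
implemented from the standard published approximations, since no
installed R package provides it) is informative only. No multiple-testing
correction is applied, matching the declared analysis.

**Matched-control subgroups.** The effect of actually receiving a
component's message compares intervention participants whose baseline
lowest-3 include the component with control participants who *would* have
received it — membership recomputed from `select_advice_components()` on
baseline scores, so it is reproducible and order-invariant. Subgroups
with fewer than 3 participants on either side are flagged non-estimable
rather than fitted.

**Power arithmetic.** `power_sample_size()` uses the two-arm normal
approximation with per-arm ceiling: n/arm = ⌈2(z₁₋α/₂ + z_power)²/(δ/σ)²⌉
with δ the relative increase times the mean. The published basis (mean
49.58, SD 9.51, +6.5%, α = 0.05, power 0.8) yields 137/arm = 274 total.
Dropout inflation is reported under both live conventions — ×(1 + rate)
(274 → 329) and ÷(1 − rate) (274 → 343) — because a published 330 target
at 20% dropout is consistent with the multiplicative convention plus
recruitment-friendly rounding, and the formula used was not printed.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
with ground-truth labels for every planted feature:

* **Baseline scores** per component per arm from normals truncated to
  [0, 100] at the published per-arm baseline means/SDs (overall: control
  58.9 SD 12.3, intervention 56.3 SD 11.5), inverse-mapped through the
  criteria so `score_profile()` recovers the drawn scores to 1e−6.
  Truncation at generation, clamping (with counting) at intervention, so
  effect attenuation from the score ceiling is measurable, not silent.
* **Change scores** combine a regression-to-the-mean pull of strength 0.5
  toward the *population* component mean (size-weighted across arms —
  arms differ at baseline only by sampling, and pulling toward arm-specific
  means would mis-specify the covariate-adjusted analysis model), a shared
  participant-level shift (SD 7), and independent per-component noise
  (SD 15). The implied overall-score change SD, ≈ √(7² + 15²/11) ≈ 8
  points, was calibrated once against the precision of the published
  overall-effect 95% CI (effect 3.5, CI 1.19–5.78 ⇒ SE ≈ 1.17 ⇒ per-arm
  change SD ≈ 8 at n = 96/91); the table's printed adjusted-change SDs
  (2.1–2.3) are inconsistent with that CI and are not used as generative
  truth.
* **True effects** are injected additively on the score scale — uniformly
  across components (`overall_effect`) or concentrated on each
  intervention participant's 3 lowest baseline components
  (`component_effects`), mirroring how the advice actually targets.
* **Trial mechanics**: fair-coin allocation (uniform draw against 0.5) or
  exact 96/91 arm sizes; visit days jittered uniformly ±7 around the 42/84
  targets, clipped to the 41/83-day gates; 35.4% post-baseline dropout,
  with 55% of completers finishing all three FFQs; per-arm endpoint energy
  changes (intervention −1316 SD 2315 kJ/day, control −726 SD 2549).
  Baseline energy (mean 8500 SD 1500 kJ/day, a typical adult FFQ intake)
  is drawn inside each participant's EI/BMR plausibility window, and
  endpoint energy within ±7500 kJ of baseline, so *only planted*
  violations trip the QC filters.
* **Planted QC violations** each trip exactly one rule (energy at 0.3 ×
  BMR at both FFQs; a +8806 kJ jump with flat weight from a 1.2 × BMR
  baseline; a 1300 g/day porridge record), with labels in the ground-truth
  sidecar.

What it does **not** emulate: food co-consumption structure, seasonality,
differential dropout, non-normal score distributions beyond truncation,
item-level FFQ behaviour, or activity questionnaire responses. Passing
recovery tests therefore demonstrates the estimator and plumbing are
correct under the stated generative model — not that real FFQ data meet
that model.

`simulate_overall_trial()` is the lightweight counterpart for replicated
recovery studies: it draws only the overall score and its change under
the same pull/noise model.

## Numerical choices and problem sizes

* All randomness flows from a single integer seed; identical config + seed
  gives byte-identical datasets (verified down to written files).
* Degenerate inputs fail loudly: equal criterion thresholds, negative
  amounts, missing components (named in the error), constant samples in
  the normality tests, sub-3-participant arms.
* Table output rounds half-up to one decimal; JSON output keeps full
  precision.
* Test-suite problem sizes: 1000 random criteria for the scoring
  properties; a 1000-participant cohort with ~12% planted violations for
  the QC oracle check; 500 replicate trials at n = 96/91 for parameter
  recovery (mean estimate within 0.2 of the injected 3.5; CI coverage
  required in [93%, 97%] — at 500 replicates the binomial noise of a
  correctly calibrated interval stays comfortably inside that band).

## Known limitations

* The shipped criteria and feasibility limits are documented stand-ins;
  analyses of real data should supply the instrument's own tables.
* The sqrt transform is applied to scores, with changes formed on the
  transformed scale; effects for transformed components are therefore on
  the √score scale, as in the published component tables.
* The energy covariate is applied to component outcomes as well as the
  overall score (the declared analysis covers "the m-AHEI analysis";
  switchable via `default_outcome_specs(component_energy_covariate =
  FALSE)`).
* Baecke scoring uses the simple item-mean variant described above, not
  the original sport-intensity composite.
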