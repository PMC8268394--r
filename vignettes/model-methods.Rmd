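---
title: "Model and methods: PAP monitoring cost-effectiveness in NYHA III heart failure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamcea)
```

## The decision problem

Implantable pulmonary-artery-pressure (PAP) monitoring lowers heart-failure
(HF) hospitalization rates in NYHA class III patients, but the device is
expensive relative to Argentine payer budgets. The package implements a
four-state Markov cohort model (stable NYHA III, HF admission,
post-admission, death; monthly cycles; lifetime horizon) that weighs the
upfront device, implantation and complication costs against averted
admissions, their costs, their excess mortality, and quality-of-life
differences, separately for the Social Security (SS) and Private Sector
(PS) payer perspectives. The comparator is usual medical care.

Death is evaluated first within each cycle; admission applies to survivors.
An admission month always ends, for survivors, in the post-admission state,
where mortality remains elevated and a new admission can occur. There is no
half-cycle correction (none is used in the source analysis), and the cohort
is closed — results are expected values per patient.

## Parameters

`reference_parameter_fixture()` carries the published base case; the same
values ship as a plain-text config in
`inst/extdata/reference_parameters.yaml`. The load path validates every
invariant (probabilities and utilities in [0, 1], non-negative rates, costs
and hazard ratios, entry age in [18, 100], ordered uncertainty bounds).

The parameters that matter most:

| Parameter | Base | Units / range |
|---|---|---|
| Entry age | 66 | years (95% CI 61–69) |
| HF admission rate, control | 1.13 | /patient-year (0.68–1.55) |
| Admission HR, device arm | 0.48 | (0.38–0.67), first 60 months |
| Mortality HR in (post-)admission | 3.32 | on the monthly background hazard (1–5) |
| Procedural mortality / complications | 0.004 / 0.03 | upfront, device arm |
| Baseline utility | 0.711 | both arms; admission disutility 0.045 |
| Device + implant (SS) | 1,392,182 + 100,878 | ARS, upfront |
| Admission cost | 362,788 (SS) / 534,983 (PS) | ARS per admission month |
| Discount rate | 5% | per year, `(1.05)^(-t/12)` per cycle |

Two source-internal wrinkles are handled explicitly. The device price
appears in the source once as 1,392,182 and once as 1,398,182; the
machine-readable parameter table's value (1,392,182) is the base case. The
willingness-to-pay thresholds are 1 / 3 / 5 GDP per capita = ARS 700,473 /
2,101,419 / 3,502,363 (3 × 700,473 is exactly 2,101,419; a conflicting
pairing elsewhere in the source is treated as a typographical slip).

## Background mortality and calibration

National Argentine life tables are not reproduced in the source, so
`make_gompertz_life_table()` generates a stand-in:
`q(age) = 1 − exp(−α·exp(β·age))` with α = 2·10⁻⁵, β = 0.101, terminal age
110 (q forced to 1). These defaults give adult mortality of the right order
for a South American population (q at 66 ≈ 0.016) and the canonical
log-linear rise of adult mortality. The table is synthetic: it matches the
*level* of adult mortality but not the exact old-age shape of the national
table, and every downstream difference from the published numbers traces
mainly to this (see "Fidelity" below).

HF excess mortality enters as a single **correction factor** multiplying the
monthly background hazard (hazard-scale multiplication keeps probabilities
in [0, 1] for any factor). `calibrate_correction_factor()` finds the factor
by bracketed bisection on [1, 100] (deterministic; tolerance 10⁻⁶ on the
target probability) such that the *full* control-arm cohort model — not the
stable state alone — reaches 23% cumulative mortality at 18 months, the
control-arm mortality observed in the pivotal trial. Calibrating on the full
model is deliberate: the published factor calibrates the model's observable
mortality, which includes the elevated mortality of admission months. On the
default life table the result is ≈ 7.96, in the vicinity of the published
7.7. Ages advance in exact monthly steps; the annual q of the integer age
applies throughout that year (no within-year interpolation). The device
arm's 16% 12-month mortality is used as a validation check only, not as a
second calibration constraint.

## Utilities

Both arms start at 0.711. Monthly changes (+0.001 / −0.005 for months 1–6,
+0.003 / −0.003 for months 7 onward, device/control) are applied through
month 12; the month-12 value is carried forward to month 60; from month 61
both arms take the control arm's held value. This "carry-forward" convention
is the package default because applying the 7-to-60 monthly drift literally
(available as `utility_mode = "drift_to_60"`) contradicts the published
6- and 12-month anchors: it would push the device arm's utility *up* to
0.879 and the control arm down to 0.519 by month 60, roughly quadrupling
the incremental QALYs relative to the published 0.37. The drift mode is
retained for sensitivity exploration, not as a candidate base case — even
though it happens to fit the published *control-arm* QALY cells a little
better, it is irreconcilable with the published incremental results.

Admission months take utility − 0.045. QALYs accrue as occupancy-weighted
utility × 1/12 per cycle.

## Treatment-effect scenarios

* `BASE_60M` — admission HR 0.48 for months 1–60, then 1.
* `LIFETIME` — HR 0.48 at every cycle. The utility difference between arms
  is also allowed to persist (no month-60 convergence). Rationale: the
  month-60 convergence exists *because* the base case assumes the treatment
  effect ends at five years; a scenario that extends the treatment effect
  to lifetime extends all of it. The HR-only variant was examined and sits
  much further from the published scenario result.
* `DECLINE_18_TO_60` — HR 0.48 through month 18 (the trial follow-up), then
  linear interpolation on the HR scale to 1 at month 60.

## Costs

Upfront, device arm, at model entry (cycle 0, undiscounted): device +
implantation + complication probability × weighted complication cost. All
implanted patients accrue these, including the 0.4% who die procedurally.
The "(1–7 month)" annotation on the complication and procedural-mortality
inputs is collapsed to model entry for simplicity. Recurring: monthly
standard-of-care cost in all alive states (both arms); the admission cost
per admission month; monthly monitoring cost in all alive device-arm months
for the whole horizon (`monitoring_duration_months = Inf` — the device
remains implanted; a finite cutoff is available, and switching it to 60
months moves the base-case ICER by under 1%). Death costs nothing.

## Sensitivity analyses

**One-way (tornado).** Each parameter is set to its low/high value
(95% CI bounds; ±1 SD for utilities; min–max for costs) with everything
else at base. The calibrated correction factor is held fixed *except* when
the varied parameter itself drives control-arm mortality (`entry_age`,
`hr_mortality_admission`, `baseline_hosp_rate`), where calibration is
re-run so the control arm keeps matching the 18-month trial anchor; the
`recalibrated` column of the output flags this per parameter. A structural
consequence worth knowing: because the model's only mortality benefit flows
through averted admissions, pushing the admission-mortality HR to 1.0
removes that channel entirely and produces a wide tornado bar for that
parameter — wider relative to the others than in the published figure.

**Probabilistic.** 1000 Monte Carlo draws (as published). Distribution
families follow the published table with two remappings forced by support:
the admission rate (1.13 > 1) is gamma, and the signed monthly utility
changes are normal — a beta variate can do neither. Betas are
moment-matched to base + SD (CI half-width / 1.96 where only a CI is
given); lognormal HRs take the log-SE from the CI (for the asymmetric
mortality-HR range 1–5, the printed range is read as a 95% interval on the
log scale — an imperfect but explicit fit); costs are normal with SD =
(max − min)/(2 × 1.96), the min–max range being treated as a 95% interval
(it equals base ± 25% throughout). The sampled entry age is rounded to an
integer year for life-table lookup. Invalid draws (negative costs, HR ≤ 0,
probabilities outside [0, 1]) are rejected and redrawn, with counts
reported. The correction factor is recalibrated within each draw (default)
so every sampled cohort still honours the trial mortality anchor; a
fixed-factor mode exists. The two perspectives are run as separate analyses
with their own seeds, as published; passing the same seed to both reuses
the identical clinical/utility draw stream if a paired comparison is
wanted. All stochastic outputs are bit-reproducible under a fixed seed.

**CEAC.** P(cost-effective at λ) = fraction of draws with
λ·ΔQALY − ΔCost > 0, on a default grid of 0–6 GDP per capita in 0.1-GDP
steps.

## Validation oracle

`simulate_individuals()` is an independent individual-level microsimulation
applying the identical transition, utility and cost rules. The test suite
runs 200,000 patients over a 240-cycle horizon and requires the
deterministic trace and accruals to agree within three Monte Carlo standard
errors; with all hazards zeroed the two agree exactly. The pooling module
is cross-checked against `metafor` on simulated study sets, and coverage of
the pooled CI is verified over 500 simulated trios.

## Numerical choices and degenerate inputs

Bisection (not derivative-based root finding) for calibration: the target
function is monotone and cheap, and bisection is deterministic. Calibration
errors out, with diagnostics, when the target is unreachable within factors
[1, 100]. ΔQALY = 0 yields an undefined ICER marker rather than a division;
sign-discordant deltas set a dominance flag. A zero discount rate makes
discounted and undiscounted totals identical. Lifetime horizon means "to
age 110", where survivorship is < 10⁻⁶ for any plausible calibration. Test
problem sizes (200,000-patient microsimulation at 240 cycles, 1000-draw
PSAs, 500-replicate coverage runs) keep the full suite under a minute of
compute while leaving Monte Carlo error well below the asserted tolerances.

## Fidelity to the published analysis, and limits

What the passing tests show: the model reproduces the published base-case
ICERs, incremental costs and QALYs (both perspectives, discounted and
undiscounted), the −25% device-price one-way result, and the SS
acceptability probability at 5 GDP within the package's stated tolerances,
with a calibrated correction factor close to the published 7.7. What they
do not show: exact reproduction. The synthetic life table lives longer at
old ages than the national table evidently does — the control arm survives
roughly 20% longer here — which inflates both arms' absolute QALYs,
leaves incremental results only mildly affected, and is the main reason the
lifetime-effect scenario ICER and the PS acceptability probability at
3 GDP sit just outside their reproduction bands. Real-data caveats carry
over from the source: treatment effects beyond 18 months are assumption,
not observation; non-HF admissions and drug adverse events are excluded by
design; and the utility trajectory is linear by construction.
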