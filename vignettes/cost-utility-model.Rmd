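---
title: "A Markov cohort cost-utility model for pharmacist-managed warfarin therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-utility model for pharmacist-managed warfarin therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warfarinCEA)
```

## The decision problem

Patients with a mechanical mitral valve prosthesis need lifelong warfarin.
Anticoagulation quality is summarised by the time in therapeutic range
(TTR): the fraction of follow-up during which the INR sits inside the
2.5–3.5 target band recommended for this valve position. Pharmacist-managed
warfarin therapy (PMWT) — structured education plus pharmacist-led dose
adjustment — improves TTR relative to standard clinic care; the economic
question is whether the downstream reduction in bleeding, thromboembolic
(TE) and reoperation events makes PMWT cost-effective or outright
cost-saving from a medical provider's perspective.

`warfarinCEA` implements that evaluation as a reusable pipeline: a
deterministic Markov cohort model over nine health states, Rosendaal TTR
scoring for patient-level INR series, one-way sensitivity analysis over
every ranged input, and a seeded synthetic trajectory generator standing in
for patient-level trial data.

## Model structure

The cohort occupies nine mutually exclusive states: three no-event INR
states (`WithinRange`, `BelowRange`, `AboveRange`), three acute event
states (`Bleeding`, `TE`, `Reoperation`), two recovery states, and
absorbing `Death`. The published state list names a single "recovery"
state while counting nine states in total; we resolve the ambiguity by
splitting recovery by the preceding event class (`RecoveryPostTE` vs
`RecoveryPostBleedOrReop`). That split also gives the two excess-mortality
risk ratios ("additional to death from any cause"; 2.25 after major TE,
1.5 after major bleeding) a mechanistic home: they multiply the
recovery-state background mortality of 0.00147 per cycle. An alternative
reading (an explicit entry state) exists but has no parameter support in
the input table.

Cycles are one month. Each arm's INR block uses its own four transition
probabilities (within→below, within→above, below→within, above→within)
with the stay probability as the row remainder; the event risks feeding
the model — above-range→bleeding 0.0115 and below-range→TE 0.0023 per
cycle — are arm-independent literature values. Event rows use the
published recurrence and death probabilities with the remaining mass
flowing to the matching recovery state; recovery is quasi-absorbing (no
return to the INR states), with recurrent events flowing back to the event
states. The three no-event INR states carry no background mortality: the
input table lists no such transition, so death is reached only through
events and recovery.

Out-of-range INR is asymptomatic in itself, so `BelowRange` and
`AboveRange` share the within-range utility (0.987); the event and
recovery utilities are as published, death is 0. Costs attach only to the
event states (bleeding 2,777.78, TE 2,314.81, reoperation 16,203.70 USD)
and are charged per cycle of occupancy; with event-state stay
probabilities of at most 0.09 this is within a few percent of charging
once per entry, and the toggle (`settings$cost_timing = "per_entry"`) is
exposed and tested.

Accumulation is trapezoidal half-cycle corrected: the effective occupancy
of cycle $t$ is the mean of the cycle-start and cycle-end rows. Both
QALYs and costs are discounted at the published 3.5% annual rate with
monthly compounding, $(1+r)^{-t/12}$, anchored at cycle 0.

## The lifetime horizon

"Lifetime" must be quantified. We calibrate the horizon so the
intervention arm — which spends essentially all of its time at utility
0.987 and is therefore pinned by the closed-form geometric series
$\frac{u}{12}\sum_{t=0}^{H-1}(1+r)^{-t/12}$ — reproduces its published
total of 21.53 discounted QALYs. With the event pathways included (about
7% of the intervention cohort drains into recovery, utility 0.668, over
the horizon), that criterion selects **540 cycles = 45 years**, which
lands at 21.598 QALYs (+0.3%) and is demographically sensible: the cohort
enters at a mean age of 46.4, so the model follows it to roughly age 91.
A 480-cycle (40-year) horizon, the value suggested by the no-event closed
form alone, gives 20.60 (−4.3%). The horizon remains a setting
(`settings$horizon_cycles`).

## What the model does and does not reproduce

At the frozen configuration the model yields, per patient (discounted):

| arm | QALYs | cost (USD) |
|---|---|---|
| intervention (PMWT) | 21.598 | 536.71 |
| control | 19.533 | 1,507.27 |

The intervention arm's published QALY total (21.53) is reproduced to
0.3%. The qualitative headline result is reproduced exactly: the
intervention arm accumulates more QALYs at lower cost, i.e. PMWT is the
dominant, cost-saving strategy, and no one-way parameter extreme
overturns cost-effectiveness.

The published control-arm totals (10.43 QALYs, 1,242.25 USD) — and hence
the published differences (−805.87 USD, 11.10 QALYs) and ICER (−72.58)
— are **not** reproducible from the published inputs under any
combination of the documented modelling options. Reaching 10.43
discounted QALYs over any plausible lifetime horizon requires a mean
per-cycle death hazard near 0.005, but the largest mortality probability
in the input set is 0.01078 per cycle (bleeding, occupied for about one
cycle per episode) and recovery mortality is 0.0022–0.0033 per cycle;
the control cohort therefore retains ~78% survival at 45 years and
accumulates ≈19.5 QALYs. Even the extreme reading that assigns utility
zero to the out-of-range INR states only reaches ≈13, while breaking the
intervention arm's published total. We conclude the published control
arm reflects additional, unpublished model mechanics; the package
reports what the published inputs imply.

Similarly, cutting the intervention arm's within-range retention by 10%
(relative, freed mass redistributed to the two exit transitions in
proportion to their base values) degrades the intervention arm but does
not break dominance here (incremental cost stays ≈ −200 USD). Pushing
all freed mass to the above-range exit does break cost dominance, but
simultaneously turns the QALY difference negative, which contradicts the
reported "very cost-effective" behaviour; no redistribution reading
reproduces it, so the proportional rule is retained as canonical.

## Sensitivity analysis

`one_way_sensitivity()` pins each of the 44 ranged parameters at its low
and high bound (all others at base), re-runs both arms, and reports the
ICER and dominance at each extreme, sorted by descending ICER span.
Published upper bounds above 1 (e.g. an initial within-range proportion
of 1.0937) are clamped into $[0,1]$ at matrix-build time, and perturbed
initial proportions are renormalised to sum to 1; an extreme that still
yields an infeasible row is flagged rather than fatal.
`classify_threshold()` applies the WHO convention against a user-supplied
GDP per capita (never hard-coded): dominant → cost-saving, ICER ≤ 1× GDP
→ very cost-effective, ≤ 3× GDP → cost-effective.

## Rosendaal TTR

`rosendaal_ttr()` linearly interpolates the INR between consecutive
measurements and apportions calendar time to in-, below- and above-range.
Within a segment, time in a band is proportional to the INR measure swept,
so crossing points are computed exactly (the suite checks agreement with a
0.001-day numerical grid to < 0.1 percentage points). Conventions: band
boundaries are inclusive; the observation window runs from the first to
the last measurement; no maximum-gap exclusion by default (visit intervals
legitimately stretch when the INR is stable), with an optional
`max_gap_days` that drops long segments from both numerator and
denominator. TTR categories follow the NICE-derived bins: `<65%` (poor
control), `65%–75%`, `>75%`, with 65 and 75 assigned to the middle bin to
keep the outer labels strict. Cohort summaries use medians and
interquartile ranges with R's default linear-interpolation quantiles.

## The synthetic cohort generator

No patient-level trial data are published, so `simulate_cohort()`
emulates the structure the analysis assumes: each patient's INR band
evolves visit-to-visit by the arm's three-band transition chain (stay =
row remainder), starting from the arm's initial proportions; visits sit
on a 30-day grid with ±3 days of uniform integer jitter (12 months, 13
visits by default, matching a one-year follow-up with "typically
monthly" INR checks); the observed INR is drawn uniformly from the
occupied band, with the unbounded tails capped at 1.2 and 6.0 for
clinical plausibility. Generation is bit-reproducible given the spec's
seed and leaves the session RNG untouched.

What passing tests show: band-occupancy structure, parameter recovery
(maximum-likelihood transition estimates within 3 binomial standard
errors of their generating values at n = 5,000), and the qualitative
trial direction (intervention median TTR above control, more control
patients under 65%). What they do not show: realism of within-band INR
values, dose–response dynamics, covariate effects, or informative visit
timing — the real trial adjusted visit intervals to INR results, which
the generator does not model.

## Numerical choices and degenerate inputs

* Matrix rows are validated to sum to 1 within 1e-12; traces conserve
  mass within 1e-9 over the full horizon.
* A computed stay-probability remainder below 0 raises an error naming
  the state row; probabilities are clamped to $[0,1]$ before assembly.
* `compute_icer()` leaves the ICER undefined (`NA`) at zero incremental
  QALYs and labels dominance from the sign pattern alone; classification
  of a dominated or undefined result never divides by zero.
* Problem sizes in the test suite — 5,000 patients for parameter
  recovery, 1,000 per arm for the TTR contrast, 2,000 for stationarity —
  were chosen so Monte-Carlo error sits well inside the asserted
  3-standard-error and 2-percentage-point bands.

## Limitations

The model inherits every simplification of the published analysis: no
age-dependent background mortality, arm-independent event risks given the
INR band, quasi-absorbing recovery, and costs restricted to the three
event types from the provider's perspective. The one-way sensitivity
analysis varies one parameter at a time; no probabilistic sensitivity
analysis is implemented. And as detailed above, the published control-arm
totals are not derivable from the published inputs, so incremental
quantities from this package should be read as "what the published input
table implies", not as a re-print of the published table of results.
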