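---
title: "The axstage decision model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The axstage decision model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axstage)
```

## The clinical question

Sentinel lymph node biopsy (SLNB) stages the axilla in early breast cancer
with far less surgery than axillary lymph node dissection (ALND), roughly
halving the risk of chronic arm lymphoedema. The price is diagnostic: SLNB
can fail to identify a sentinel node (the patient then converts to ALND), and
it can return a false-negative (FN) finding — occult metastases left behind
in unsampled nodes — which raises the long-term risk of axillary recurrence
and its downstream consequences (distant metastases, breast-cancer death).
Randomised trials (SNAC, NSABP B-32, ALMANAC, GIVOM and others) cover about
8 years of follow-up; the trade-off between a permanent quality-of-life gain
and a small, slowly compounding oncological risk plays out over decades.

`axstage` quantifies that trade-off with a Markov cohort state-transition
model: a simulated cohort of women aged 58 with early breast cancer is staged
either by an SLNB-based strategy or by routine ALND, then followed for
20 one-year cycles. Outcomes are cumulative event incidences, life years,
quality-adjusted life years (QALYs) and direct Australian health-system costs
per 1000 patients, discounted at 5% per annum.

## The staging decision tree

Each arm is split into strata before the Markov process starts
(`build_strata()`). With `p` the prevalence of node-positive disease (base
case 0.269), `f` the SLNB failure rate (0.06) and `fn` the false-negative
rate (0.055):

* ALND arm: node-positive (`p`) and node-negative (`1 - p`), both costed at
  the ALND procedure cost.
* SLNB arm: true negative `(1-p)(1-f)`; failed mapping, node negative
  `(1-p)f`; false negative `p(1-f)fn`; detected positive, completion ALND
  `p(1-f)(1-fn)`; failed mapping, node positive `pf`.

The FN rate is applied among node-positive patients whose mapping
*succeeded*: a failed SLNB converts to ALND and therefore cannot produce a
false-negative finding.

Two attributes are assigned at this stage and never change:

* **Lymphoedema.** A fixed fraction of each stratum lives with
  moderate-severe arm lymphoedema, accruing a utility decrement (0.03) and an
  annual care cost. The fraction follows the surgery actually received:
  patients whose SLNB is positive or fails undergo completion ALND and carry
  the ALND-level risk (0.176); only SLNB-staged patients who avoid ALND get
  the lower risk (0.119). Modelling lymphoedema as a baseline fraction rather
  than as separate Markov states is exact in expectation, because lymphoedema
  here affects only utility and annual cost, never transitions.
* **Recurrence profile.** The FN stratum faces the elevated annual
  axillary-recurrence probability (0.016 instead of 0.0008) until its first
  axillary recurrence; once that recurrence is treated, baseline first-event
  risks apply.

* **Adjuvant therapy.** Radiotherapy, first-line chemotherapy, 5-year
  endocrine therapy and 1-year trastuzumab are costed upfront as
  uptake-weighted lump sums. By default
  (`model_settings(differential_adjuvant_uptake = FALSE)`) the same
  (comparator-arm) uptake proportions are applied to both arms: the small
  uptake differences reported between trial arms reflect the nodal-stage
  information each staging strategy reveals rather than a cost consequence a
  decision-maker would attribute to the strategy itself, and treating them as
  differential would add a constant ~AU$316 per patient against SLNB that is
  not reflected in the incremental results this model is designed to
  reproduce. Set the flag to `TRUE` to cost each arm with its own printed
  uptakes.

## Health states and transitions

The public state space is disease free, local recurrence, axillary
recurrence, distant metastases, death from breast cancer (reachable only
from distant metastases) and death from other causes (reachable from every
alive state).

Internally the disease-free and recurrence states are tiered by recurrence
history, for two reasons:

1. **Recurrences are 1-year tunnel states.** A patient entering local or
   axillary recurrence spends exactly one cycle there (utility 0.911,
   one-off treatment cost), then either progresses to distant metastases,
   dies of other causes, or returns to disease free.
2. **Recurrence history permanently elevates metastatic risk.** After
   returning to disease free, the annual probability of distant metastases is
   the "after local recurrence" (0.1246 node-positive / 0.0772 node-negative)
   or "after axillary recurrence" (0.2063 / 0.2259) value, permanently, with
   axillary history dominating local. Without this memory the model would
   need the recurrence year itself to carry essentially all metastatic
   consequences of a recurrence, which is clinically wrong (a treated
   locoregional recurrence marks a persistently high-risk patient) and
   numerically far too mild: downstream distant metastases and deaths would
   shrink by an order of magnitude relative to the incidence levels the
   parameter sources describe.

First-event local and axillary recurrence probabilities follow the
calibration that recurrence risk is front-loaded: they halve after year 5 and
halve again after year 10 (`halving_factor()`). The annual FN recurrence
probability 0.016 corresponds to a 5-year cumulative risk of
`1 - (1 - 0.016)^5` = 7.75%, the figure derived from the excess nodal
recurrences in the SLNB arm of NSABP B-32. First-event distant-metastasis
probabilities are not time-varying.

Competing risks within a state are applied as printed marginal annual
probabilities, additively, with a feasibility check that each row sums to at
most 1 (an infeasible draw names the state and cycle). No rate conversion is
attempted: the sources publish probabilities, and the values are small.

## Accrual conventions

* **Half-cycle correction.** Utilities and annual state costs accrue on the
  average of the state occupancies at the two boundaries of each cycle.
  One-off transition costs (recurrence treatment, end-of-life costs) apply to
  the flow of new entrants in the cycle, uncorrected — events are realised,
  and paid for, when they happen. Upfront surgery and adjuvant costs are
  accrued before cycle 1.
* **Discounting.** Cycle-`t` accruals are multiplied by `1.05^-t`
  (end-of-cycle factors); upfront costs are undiscounted. Setting
  `discount_rate = 0` makes discounted and undiscounted outputs identical,
  which the tests assert.
* **Ages.** Cycle `t` uses the other-cause mortality of age `58 + t - 1`,
  so the cohort ages from 58 to 77 over the horizon.

## Background mortality

The annual probability of death from causes other than breast cancer is a
built-in Gompertz schedule `q(age) = q0 exp(b (age - 58))` over ages 58-78
(`default_mortality_schedule()`), approximating early-2000s Australian female
all-cause mortality with breast-cancer deaths excluded. Its two coefficients
were calibrated so that the ALND arm accumulates 18.4 other-cause deaths per
1000 patients by year 5 and 160 per 1000 by year 20, the values the rest of
the parameter set was derived alongside; the resulting schedule rises from
about 0.0030 at age 58 to about 0.022 at age 77. Incremental (SLNB - ALND)
results are insensitive to this schedule because it applies identically to
both arms; arm-absolute life-year and cost totals do depend on it, which is
why the package's validation targets are the incremental quantities. A custom
schedule can be supplied via `parameter_set(other_cause_mortality = ...)` or
the YAML configuration.

## Sensitivity machinery

* **One-way thresholds** (`one_way_threshold()`): bisection on a single input
  for the root of the 20-year discounted incremental QALYs (or costs), all
  else at base case, stopping when the absolute incremental outcome falls
  below `tol` (default 0.001 per 1000) or the parameter interval is below
  1e-6. Same-signed bounds return a non-converged result rather than an
  error. Bisection was implemented directly (rather than through a generic
  root finder) because the non-convergence contract and the audit fields of
  the result are part of the interface; tests confirm every threshold against
  a 201-point dense grid scan. The 5-year cumulative recurrence risk given FN
  is searched on the cumulative scale and mapped to the annual probability
  via `annual = 1 - (1 - cum5)^(1/5)`. Search bounds extend beyond the
  tabulated sensitivity ranges where the crossing lies outside them (the
  node-positive threshold, near 0.5, exceeds the tabulated high of 0.46).
* **Preference planes** (`multiway_plane()`): 3x3 panels of FN rate by
  5-year FN recurrence risk; each panel grids lymphoedema probability after
  ALND against lymphoedema disutility and shades each cell by the strategy
  with more discounted QALYs. Default axes are the tabulated sensitivity
  ranges and the default resolution is 41x41 (sub-1% steps at negligible
  cost). Arm QALYs are exactly affine in the disutility, so each column is
  computed from full model runs at the two ends of the disutility axis and
  interpolated exactly in between; a test verifies the interpolation against
  a direct run. Cells with |incremental QALYs| < 1e-10 are reported as ties.
* **Tornado** (`tornado()`): every probability/utility over its tabulated
  range and every cost over +/-20%, sorted by output swing, with a flag for
  whether the preferred strategy survives both ends.

## The microsimulation oracle

`simulate_arm()` draws individual patients through the same decision tree and
yearly transition rules, implemented independently of the cohort engine (its
own staging draw and its own inline transition logic — a shared
transition-matrix would make the comparison circular). Patients accrue
utilities and annual costs for the state occupied at the start of each year,
without half-cycle correction, with events realised at year end; the
expectation of this process equals a cohort run with
`half_cycle_correction = FALSE` exactly, and the tests assert agreement
within 3 Monte-Carlo standard errors at n = 200,000 for five random parameter
sets, plus an explicit bound on the half-cycle discrepancy against the
corrected engine. `draw_parameter_sets()` supplies those random sets: uniform
draws within each tabulated low-high range (the sources publish ranges, not
distributions) and +/-20% for costs, feasibility-checked with bounded
redraws. It exists to exercise the machinery, not to report probabilistic
sensitivity results.

What the oracle does and does not show: agreement demonstrates that the
cohort recursion, accrual arithmetic, discounting and staging tree are
implemented consistently under two independent codings of the same rules. It
cannot validate the rules against reality — the synthetic trajectories
inherit every structural assumption (annual cycles, tunnel states,
permanent post-recurrence risk, baseline-assigned lymphoedema), so passing
tests say nothing about, for example, anxiety or surgical-delay harms, which
are outside the model.

## Numerical choices and degenerate inputs

* Stratum weights must sum to 1 within 1e-12; cohort mass is checked every
  cycle at the same tolerance.
* `p_slnb_fail = 0, p_slnb_fn = 0` collapses the SLNB arm to the ALND nodal
  split; with equal lymphoedema risks and equal surgical costs the arms are
  identical and all differences are zero to machine precision (the symmetry
  null test).
* Dominance classification uses a 1e-10 tie tolerance; otherwise "SLNB
  dominant", "ALND dominant", or an ICER when one strategy is both more
  effective and more costly.
* Horizons beyond age 78 extrapolate the mortality schedule geometrically
  with its last observed ratio.

## Problem sizes

The base-case cohort comparison (7 strata, 20 cycles) runs in well under a
second; the full threshold set takes a few seconds; a 41x41x9 plane scenario
takes on the order of a minute; the validation suite uses n = 200,000
microsimulated patients per arm. These sizes are the package defaults and
are the sizes at which all reported numbers were computed.

## Known limitations

* Lymphoedema onset is immediate and permanent; trials measured prevalence
  around 3 years, so early-cycle lymphoedema-year counts are upper bounds.
* The model excludes contralateral disease, second primaries, patient and
  societal costs, and the anxiety/delay harms of staged surgery.
* The recurrence utility (0.911) is shared by local and axillary recurrence,
  and adjuvant therapy costs are lump sums (the 5-year endocrine course is
  not spread over cycles); both choices mirror how the source estimates were
  published.
* Repeat recurrences reuse the first-event probabilities (with the same
  halving), and a local recurrence after an axillary one keeps the
  (higher) post-axillary metastatic risk; both affect a vanishing fraction
  of the cohort.
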