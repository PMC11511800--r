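---
title: "Modelling the cost-effectiveness of digital fall-preventive exercise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of digital fall-preventive exercise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallcea)
```

## The decision problem

About a third of people over 65 fall each year, and the consequences scale
from a bruise to a hip fracture, long-term residential care and death. A
fully self-managed digital exercise programme (balance and strength
training delivered through an app) is cheap to provide at scale, but does
preventing some first-year falls justify its recruitment, support and
maintenance costs once the long-term consequences of falls are accounted
for? `fallcea` answers this with a Markov cohort model comparing the
programme against doing nothing, from a societal costing perspective.

## Model structure and assumptions

A closed cohort (no entries after time zero) of `n = 173` persons, mean
age 76, occupies five states: **A** at risk for a fall, **B** minor fall
consequences (emergency visit, no admission), **C** major fall
consequences (admission, e.g. hip fracture), **D** special housing after a
fall, and **E** death. Transitions happen once per annual cycle under a
row-stochastic matrix; death is absorbing, and from special housing only
remaining there or dying is possible (recovery out of long-term care is
treated as negligible). Everyone starts in A.

The key structural assumptions, inherited from the falls literature the
transition probabilities come from:

* transition probabilities are constant over time except for background
  mortality (below); in particular fall risk itself is not escalated with
  age, a known conservative simplification;
* the cohort is not stratified by sex;
* occupancy is propagated as expected values (fractional persons), which
  is exact for the mean of the underlying individual-level process.

## Transition probabilities and age-adjusted mortality

The baseline annual matrix (`fall_transition_matrix()`) encodes, per row:
population fall and long-term-care statistics (row A), re-fracture risks
after a wrist fracture (row B), recovery, institutionalisation and
one-year post-hip-fracture mortality (row C), and long-term-care mortality
(row D).

The A→E and B→E entries are the *background* mortality of a 76-year-old
(0.03/year) and must grow as the cohort ages. National life-table values
are jurisdiction- and year-specific, so the package ships a parametric
schedule instead (`gompertz_schedule()`):

$$q(a) = \min\{1,\; q_0 e^{b (a - a_0)}\}, \qquad q_0 = 0.03,\; a_0 = 76,\; b = 0.08/\text{yr},$$

an exponential (Gompertz-type) hazard anchored exactly at the printed
baseline. A doubling time of $\log 2 / 0.08 \approx 8.7$ years matches the
roughly 8–9-year doubling of all-cause mortality observed in Northern
European old-age life tables over ages 76–88. Any tabulated schedule can
be substituted via `mortality_schedule()`; the sensitivity of results to
this choice is examined below.

Cycle $t$ uses age $a_0 + t - 1$, so cycle 1 reproduces the baseline
matrix exactly (the anchor equals the printed 0.03). When the schedule
raises the death probability, the increase is deducted from the
"recovery" entries A→A and B→A — the largest and most favourable
transitions — keeping rows stochastic; `compensate = "proportional"`
rescales all non-death entries instead. If a very high schedule value
would drive the donor entry negative, the donor is clamped at zero and
the remaining non-death mass is rescaled proportionally, with a warning.
Rows C and D are *event-conditional* death risks (after hip fracture,
in long-term care) and are never age-adjusted.

## The intervention

The programme's effect enters as a fall **rate ratio** RaR = 0.76 (a 24%
reduction in the rate of falls, from meta-analytic evidence on balance and
functional exercise), applied multiplicatively to the consequential-fall
transitions A→B, A→C and B→C. The probability mass removed from row A
returns to A→A, and from row B to B→A. The effect is assumed to last one
year only (`effect_duration = 1`); cycles 2–12 of the intervention arm use
the no-intervention matrices, identically age-adjusted.

Two application modes exist because of rounding:

* `"table"` (base-case default): the modified entries are rounded to two
  decimals, giving the whole-percent first-year matrix
  (A: 0.77/0.05/0.10/0.05/0.03, B: 0.64/0.13/0.15/0.05/0.03);
* `"exact"`: unrounded products, used automatically by the sensitivity
  scenarios — a ratio of 0.98 applied to 0.07 rounds straight back to
  0.07, so whole-percent rounding would erase small effects entirely.

The intervention costs €121 per participant, charged once at time zero,
undiscounted and outside the half-cycle correction (an acquisition cost,
not a state payoff). The ledger behind it (`build_cost_ledger()`) spreads
cost totals over the 173 participants: recruitment €52 (brochure, bus
advertisement, oral presentations), supportive strategies €42 (group
sessions, drop-in support) and application maintenance €27. Category
per-participant costs are rounded *up* to the next whole euro and the
grand total is the sum of the rounded categories — the convention under
which the published whole-euro category figures (52 + 42 + 27 = 121, and
78 for a recruitment campaign scaled by 1.5) are all reproduced exactly;
no nearest-integer rule applied uniformly at component level does so.
Component-level per-participant values are reported nearest-euro for
information only.

## Outcomes, half-cycle correction and discounting

Each state carries an annual utility (QALY weight) and societal cost
(`fall_state_payoffs()`; December-2021 euros, covering regional care,
municipal care and informal care; the at-risk state and death carry no
cost). Transitions happen in continuous time within a year, so crediting
a full year at either the start- or end-of-cycle occupancy biases the
totals; the conventional **half-cycle correction** credits the cycle
midpoint, implemented as the trapezoid

$$\bar{x}_t = \tfrac12 (x_{t-1} + x_t),$$

applied to both QALYs and costs (`timing = "start"/"end"` are available
for closed-form checks, and the half-cycle total provably lies between
them). Cycle $t$ outcomes are multiplied by the discount factor $1$ for
$t = 1$ and $(1.03)^{-(t-1)}$ afterwards — the "discount after the first
year" convention; `discount_first_year = TRUE` switches to discounting
from year one.

Incremental results compare the intervention arm (reference) with no
intervention: *dominant* if it gains QALYs and saves money, *dominated*
in the mirror case, otherwise ICER = ΔC/ΔE (undefined and signalled when
ΔE = 0). The ICER is kept unrounded internally and rounded to whole euros
only for presentation.

## Scenarios

`run_all()` evaluates the base case and three one-parameter-at-a-time
deterministic scenarios — RaR 0.84 (the mean effect of a comparable
digital exercise trial), recruitment ×1.5, and RaR 0.98 (that trial's
upper confidence limit) — against a single shared comparator arm:

```{r scenarios}
report <- run_all(fall_model())
report[, c("scenario", "inc_qalys_pp", "inc_cost_pp", "verdict", "icer")]
```

The first-year falls-prevented figure is truncated to whole falls (a
fraction of a fall is not a prevented fall); the unrounded expectation is
available with `fractional = TRUE`:

```{r falls}
falls_prevented_first_cycle(fall_model(), fractional = TRUE)
falls_prevented_first_cycle(fall_model())
```

## Numerical choices and degenerate inputs

* Row sums are validated to `1e-9`; trace conservation to `1e-6` persons.
* Whole-euro roundings use round-half-away-from-zero (base R's `round()`
  is banker's rounding), except the category ledger's round-up described
  above.
* The identity matrix is a *legal* transition matrix (every state
  absorbing); validation rejects only genuine structural violations.
* A cohort started in E accrues exactly zero; an all-to-death matrix
  absorbs the cohort in one cycle and credits half a year of the origin
  state under half-cycle correction.
* Scenario overrides are minimal diffs on the base model; unknown
  override targets are rejected at construction.

## Validation against an independent microsimulation

The cohort recursion computes the expectation of an individual-level
stochastic process, so the package carries that process as an oracle:
`microsimulate()` samples individual state paths and accrues discounted,
half-cycle-corrected payoffs per individual with its own trapezoid on
indicator occupancy — none of the cohort engine's matrix algebra is
reused, making agreement a genuine cross-check. The test suite requires
agreement within three Monte Carlo standard errors at 100 000 individuals
for the study model, and across twenty seeded random five-state models
(generated by `generate_random_model()`, which also backs the
property tests: conservation, row-stochasticity under every matrix
operation, rate-ratio composition, antisymmetry of the arm comparison).

```{r oracle}
m <- fall_model()
engine <- accumulate_outcomes(
  run_cohort(build_arm_matrices(m, "no_intervention"), m$config),
  m$payoffs, m$config)
ms <- microsimulate(build_arm_matrices(m, "no_intervention"),
                    m$payoffs, m$config, n_sim = 1e5, seed = 1)
c(engine = engine$qalys_per_participant, microsim = ms$mean_qalys,
  se = ms$se_qalys)
```

What the synthetic generator deliberately does *not* emulate: correlated
individual frailty, sex- or season-specific risks, or time-varying fall
rates — passing these tests shows the engine computes its model exactly,
not that the model captures every feature of real fall epidemiology.

## Sensitivity to the mortality schedule, and limitations

The shipped Gompertz schedule stands in for an unpublished national life
table, so *absolute* arm totals (QALYs ≈ 4.56, costs ≈ €106 000 per
participant for no intervention) should be read as schedule-dependent:
scaling the schedule by ±20% moves them by several percent. The
*incremental* results are far more robust — the same perturbation moves
ΔQALY and ΔC by under 5% of their values, an order of magnitude less than
the shift in the arm totals in absolute terms — because both arms share
the identical mortality and the increments difference it away. The test
suite pins this property down quantitatively.

Remaining limitations mirror the model's scope: no probabilistic
sensitivity analysis (the scenarios are deliberate stepwise variations),
no rising fall risk with age, no sex stratification, one-year intervention
effect with no decay curve, and literature-derived transition
probabilities that pool age groups above 60. The per-participant ICER of
the conservative scenario computed from this engine (€7 624) differs
slightly from the €7 616 obtained by dividing the published rounded
totals (6 375 / 0.837); both arise from the same arithmetic at different
rounding points, and both sit two orders of magnitude below a €100 000
per-QALY threshold.
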