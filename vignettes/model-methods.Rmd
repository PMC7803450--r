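---
title: "Methods: a Markov cohort cost-utility model for treating stage 1 hypertension by CVD risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort cost-utility model for treating stage 1 hypertension by CVD risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htnce)
```

## The decision problem

People with stage 1 hypertension (clinic blood pressure 140–159/90–99 mm Hg)
and no established cardiovascular disease (CVD) face a choice: start
antihypertensive drug treatment now, or wait. Drug treatment lowers the risk
of CVD events but carries drug, monitoring and adverse-event burdens every
year it is taken. Because the *absolute* benefit scales with baseline risk
while the burdens do not, there is some 10-year CVD risk below which
treatment stops being worth its cost at a given willingness to pay per
quality-adjusted life-year (QALY). This package implements a lifetime Markov
cohort model to locate that risk level, together with the machinery around
it: probabilistic sensitivity analysis (PSA), scenario grids over age, sex
and risk subgroup, and a crude 10-year number-needed-to-treat companion
calculation.

## State space and transitions

The cohort occupies 15 states: event-free ("well"); an event-year tunnel and
a post-event state for each of six nonfatal first events (stable angina,
unstable angina, myocardial infarction, stroke, transient ischaemic attack,
heart failure); and absorbing CVD-death and non-CVD-death states. The tunnel
states exist to carry first-year costs and utility decrements; after exactly
one cycle their occupants move to the matching post-event state (or die).
Repeat events are deliberately not modelled — a person who has had one event
stays in its post-event state until death, with post-event annual costs that
proxy downstream care. Fatal first CVD events are one category of the
first-event distribution and send their share of the well state directly to
CVD death.

Cycles are one year, ages advance one year per cycle from the starting age,
and the model runs for at most 60 cycles (to age 100 from the default
starting age of 60) or until the lifetable runs out at age 115, whichever is
sooner. One consequence worth noting: with all event risks and mortality set
to zero the transition matrix is *not* the identity — the tunnel rows still
flush into their post-event states, because tunnels are defined by structure,
not by hazard.

## Risk calibration

The annual probability of a first CVD event grows additively with age:
$p(t) = p_1 + (t-1)\,\delta$. Given a 10-year risk $r_{10}$ and increment
$\delta$, the starting probability $p_1$ is the root of

$$1 - \prod_{t=1}^{10}\bigl(1 - (p_1 + (t-1)\delta)\bigr) = r_{10}.$$

The left side is strictly increasing in $p_1$, so `solve_first_event_risk()`
uses plain bisection on $(10^{-12},\, 1 - 9\delta - 10^{-12})$ to a tolerance
of $10^{-12}$; for $\delta = 0$ the closed form
$p_1 = 1 - (1-r_{10})^{1/10}$ is used. The calibration has one equation and
two unknowns, so $\delta$ must be supplied; it is an explicit input
(default 0.001/year in the synthetic base case, i.e. +0.1 percentage points
of annual risk per year of age) rather than something inferred. Two
consequences are surfaced as explicit errors or flags:

* **Feasibility.** If $\delta$ alone compounds past $r_{10}$
  (about $45\delta > r_{10}$ over 10 years) no root exists and the solver
  raises an infeasibility error. This also bounds threshold searches from
  below: at $\delta = 0.001$ no cohort can have a 10-year risk under ~4.4%,
  which is why `find_threshold_risk()` defaults its bracket to
  $[0.05, 0.30]$.
* **Capping.** Beyond year 10 the same additive growth continues for the
  lifetime horizon; the per-cycle total is capped (default 0.99) with a
  warning if the schedule ever reaches it.

Each cycle's total is split across the seven event categories by the age/sex
first-event distribution of the band containing the current age.

## Mortality

Non-CVD death from any alive state uses the lifetable all-cause probability
times the non-circulatory fraction of deaths at that age and sex, so that
circulatory mortality enters only through the model's own fatal-CVD pathway.
Post-event states carry excess mortality through a standardized mortality
ratio (SMR) applied on the rate scale, $q' = 1 - (1-q)^{\text{SMR}}$, which
keeps $q' \le 1$ for any SMR (naive probability multiplication does not).
The attribution of post-event deaths between the two death states is not
identified by the model's outputs, so it is a configurable rule:
`"excess_to_cvd"` (default) sends background all-cause mortality to non-CVD
death and only the SMR excess to CVD death; `"background_split"`
additionally divides the background by the non-circulatory fraction. The
choice does not affect costs or QALYs, only the cause-of-death composition
of the trace.

## Treatment, adverse events, payoffs

While on treatment, each event category's probability is multiplied by an
effective relative risk: a base RR times a relative age transformation for
the band containing the current age (RRs are assumed constant across risk
subgroups, so absolute benefit scales with baseline risk). The treated arm
is on treatment in every alive state; the comparator arm starts treatment
only after any nonfatal event — or, in the differential-duration sensitivity
analysis, once the cycle reaches a configurable delay. When the comparator
does start treatment it receives the same RR, costs and adverse-event model.

Adverse events are modelled in expectation rather than as states: every
on-treatment person-year accrues `annual_probability × cost_per_event` in
cost and `annual_probability × disutility` in QALY decrement, including in
event-year and post-event states (the alternative — exempting event years —
is not distinguishable from available descriptions; applying it everywhere
is the simpler rule). A background off-treatment adverse-event probability
exists and defaults to zero.

QALYs multiply an age/sex baseline utility by a state multiplier; costs sum
drug + monitoring (on treatment), post-event annual costs, and expected
adverse-event costs. Both are half-cycle corrected — each cycle's occupancy
is the mean of its two boundary occupancies, reflecting mid-cycle
transitions — and discounted at 3.5%/year with the first cycle discounted at
power one. The single exception to half-cycle correction is the one-off
event-year cost, which is a within-cycle quantity applied in full to the
cohort entering an event state that cycle, so each event is costed exactly
once. A negative computed utility (possible only under extreme adverse-event
disutilities) is clamped to zero with a warning.

## Economics

`compare_arms()` reports treated-minus-comparator incremental cost and
QALYs, the ICER when the quadrant makes the ratio meaningful, a dominance
label otherwise (cheaper-and-better = dominant, dearer-and-worse =
dominated; a QALY difference below $10^{-12}$ is classified by cost sign),
net monetary benefit $\lambda\,\Delta Q - \Delta C$, and a cost-effective
flag (dominant, or positive QALY gain at ICER $\le \lambda$). The default
threshold is £20 000/QALY, the usual UK reference value.

The 10-year NNT is intentionally crude and separate from the Markov model:
$\text{NNT} = 1/(r_{10}\,(1-\overline{RR}))$ with $\overline{RR}$ the
unweighted mean of the per-category effective RRs at the starting age,
reported both raw and rounded up (with a $10^{-9}$ slack so floating-point
overshoot cannot bump the integer). The RR table carries no sex dimension,
so per-sex and pooled-sex versions coincide.

## Probabilistic sensitivity analysis

Each uncertain parameter gets a `dist_spec` whose family follows its role:
beta for probabilities and utility multipliers (method-of-moments from mean
and SE), gamma for costs, lognormal for relative risks (so uncertainty is
symmetric on the log scale), or fixed. Draws are independent across
parameters — no correlation structure is asserted — and reproducible per
`(seed, draw)` via a dedicated seed stream, with the caller's RNG state
restored afterwards. An invalid draw (e.g. an event split pushed out of the
simplex) is resampled up to a bounded retry count, then errors.
`default_psa_specs()` attaches a 20% coefficient of variation to RRs and
costs and a quarter of the distance-to-one to utility multipliers; the
first-event *composition* is held fixed because perturbing a 7-category
simplex per stratum needs a Dirichlet-style rule that the base tables do not
parameterize — a known limitation. `run_psa()` (default 5000 draws; tests
and the acceptance script use fewer) reruns both arms per draw and reports
the probability of positive net monetary benefit plus a CEAC over
£0–£50 000 in £1000 steps.

`find_threshold_risk()` bisects the 10-year risk (tolerance $10^{-4}$, far
finer than any reporting need) on the sign of net monetary benefit, after
probing five points across the bracket to verify monotonicity — a
non-monotone pattern aborts with the probe table. Boundary outcomes return
flags (`"cost-effective throughout"`, `"never within bracket"`) instead of a
root. `probabilistic_threshold()` reruns the PSA at a chosen risk; at the
deterministic threshold the probability should sit near one half, which is
what the test suite checks.

## The synthetic parameter bundle

The published base-case input tables for this class of model are not
redistributable here, so the package ships a **synthetic** bundle
(`base_case_fixture()`, and the same values as files under
`inst/extdata/synthetic_base_case/`). Values were chosen once, for
UK-plausibility of magnitude and shape, and are not calibrated to reproduce
any published result:

| Component | Synthetic choice | Rationale |
|---|---|---|
| Lifetable | Gompertz $q = a e^{b\,\text{age}}$, capped at 0.7; male $a=3.3\times10^{-5}, b=0.093$; female $a=1.6\times10^{-5}, b=0.097$ | matches UK-scale mortality around ages 60–80 |
| Non-circulatory fraction | $0.92 - 0.002(\text{age}-40)$, clamped to (0.55, 0.95) | circulatory share of deaths rises with age |
| First-event split | 5 age bands × 2 sexes; stroke/HF/fatal shares rise with age; men more MI, women more stroke | qualitative epidemiology of first CVD events |
| Relative risks | 0.72 (HF) to 0.90 (SA); age factors 0.92→1.08 across bands | scale of antihypertensive primary-prevention meta-analyses |
| SMRs | 1.5 (SA, TIA) to 3.5 (HF) | post-event excess mortality ordering |
| Utilities | baselines 0.89→0.69 by age/sex; multipliers 0.63 (stroke year) to 0.94 (post-TIA) | EQ-5D population norms and event decrement ordering |
| Costs (£, 2016/17 scale) | drug 25/yr, monitoring 110/yr; event-year 1500 (TIA) – 11 900 (stroke); post-event 100–2500/yr | generic drug pricing vs. event care costs |
| Risk increment $\delta$ | 0.001/yr | gentle additive age growth of annual risk |
| Adverse events | probability 0.02/yr on treatment, £400, disutility 0.05 | serious-adverse-event scale of large BP trials |

`random_paramset()` widens all of these into documented random ranges
(risk 2–30%, $\delta \sim U(0, r_{10}/50)$ to guarantee calibration
feasibility, random Gompertz lifetables, Dirichlet-style event splits) and
is the workhorse of the property tests: every draw must satisfy every
`paramset` invariant.

What passing tests on this bundle show is that the *machinery* is correct —
calibration inverts, mass is conserved, structural zeros hold, payoffs match
closed forms, the engine agrees with microsimulation, ICERs fall as risk
rises. What they cannot show is agreement with any published headline
number: that requires transcribing the published input tables into the
reserved `inst/extdata/supplement_transcribed/` slot, which deliberately
ships empty rather than pretending synthetic values are the real ones. The
corresponding test fails until those tables are supplied.

## Numerical choices

* Bisection tolerances: $10^{-12}$ on $p_1$; $10^{-4}$ on threshold risk.
* Transition rows are built with an explicit residual, then checked; any row
  off one by more than $10^{-9}$ is a construction error, and a well-row
  overflow (events + mortality > 1) errors rather than renormalizes.
* Discounting: $(1+r)^{-t}$ with $t=1$ for the first cycle, standard for
  half-cycle-corrected annual models; a constant-payoff cohort therefore
  reproduces the textbook annuity factor exactly, which is a test.
* Microsimulation agreement: the engine's trace is compared with a seeded
  million-person microsimulation per state and cycle. With ~300
  simultaneous binomial comparisons a flat 3-standard-error rule would fail
  a *correct* engine in most runs, so the check uses a multiplicity-corrected
  per-cell bound (family-wise 1%, about 4.3 SEs) plus a cap on how many
  cells may exceed 3 SEs (the upper 99.5% binomial quantile of the expected
  count). Any systematic engine error produces deviations of tens of SEs
  and is still caught.
* Problem sizes in the shipped tests and acceptance script — 10–12-cycle
  microsimulation fixtures, 30-cycle threshold fixtures, 1000-draw PSAs —
  were chosen so the whole suite runs in about a minute while keeping every
  Monte-Carlo comparison comfortably powered.

## Known limitations

* No repeat events, no treatment nonadherence, no per-drug-class modelling;
  drug cost is one aggregate annual figure.
* The first-event composition is fixed in the PSA (see above).
* The additive risk-growth rule is linear for life; real risk may accelerate
  in old age.
* Adverse events are expected-value only — no severity distribution, no
  discontinuation.
* The NNT calculation ignores competing mortality over the 10 years, which
  is exactly its published "crude" intent.
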