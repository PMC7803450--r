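# htnce

Lifetime Markov cohort cost-utility model for one of the central questions
in primary prevention of cardiovascular disease (CVD): **at what 10-year CVD
risk does it become cost-effective to start antihypertensive drug treatment
in stage 1 hypertension** (clinic blood pressure 140–159/90–99 mm Hg)? The
package is aimed at health economists and HTA analysts who want a fully
scriptable, testable implementation of this class of decision model.

## The model

Two strategies are compared for a cohort entering event-free at a given age,
sex and 10-year CVD risk *r₁₀*: start antihypertensive treatment now, or no
treatment (with treatment starting in both arms after any nonfatal CVD
event). The cohort moves through 15 health states in 1-year cycles for up to
60 cycles: the event-free ("well") state; an event-year tunnel state and a
post-event state for each of six nonfatal first events (stable angina,
unstable angina, MI, stroke, TIA, heart failure); and two absorbing death
states (CVD, non-CVD). Repeat events are not modelled.

Key mechanics, each implemented as an exported function:

* **Risk calibration** — the annual first-event probability grows additively
  with age, *p(t) = p₁ + (t−1)δ*, with *p₁* solved by bisection so the
  schedule compounds to *r₁₀* over 10 years:
  `1 − ∏ₜ (1 − (p₁ + (t−1)δ)) = r₁₀` (`solve_first_event_risk`). Each
  cycle's total is split across event categories by an age/sex distribution
  of first events.
* **Mortality** — non-CVD death uses lifetable probabilities scaled by the
  non-circulatory fraction of deaths; post-event mortality applies a
  standardized mortality ratio on the rate scale,
  *q′ = 1 − (1 − q)^SMR* (`post_event_death_prob`).
* **Treatment** — relative risks per event category, adjusted by relative
  age transformations, applied to the well-state event probabilities while
  on treatment; adverse events enter as an expected annual cost and
  disutility on treated person-years.
* **Economics** — QALYs (age/sex baseline utilities × state multipliers)
  and costs (drug + monitoring, one-off event-year costs, post-event annual
  costs) are half-cycle corrected and discounted at 3.5%/year; strategies
  are compared by ICER = ΔC/ΔQ and net monetary benefit at a
  willingness-to-pay threshold λ = £20 000/QALY (`compare_arms`).
* **Uncertainty** — probabilistic sensitivity analysis with role-appropriate
  distributions (beta for probabilities/utilities, gamma for costs,
  lognormal for relative risks) and CEAC output (`run_psa`), and a bisection
  search for the risk at which treatment becomes cost-effective
  (`find_threshold_risk`).

All inputs live in a `paramset` loaded from a YAML config plus CSV tables
(`load_paramset`/`save_paramset`). The package ships a clearly labelled
**synthetic** base-case bundle (`base_case_fixture()`,
`inst/extdata/synthetic_base_case/`) with UK-plausible magnitudes; it is a
structural stand-in, not the published inputs, so absolute results
illustrate the machinery rather than reproduce published numbers.

## Worked example

```r
library(htnce)

p <- base_case_fixture(age = 60, sex = "male", r10 = 0.10)
res <- evaluate_paramset(p)
res
#> <ce_result>
#>   incremental cost       1487.41
#>   incremental QALYs      0.09996
#>   ICER              14880 per QALY
#>   NMB at 20,000: 511.79 (cost-effective)

find_threshold_risk(p)$risk
#> [1] 0.07371216

run_psa(p, default_psa_specs(p), n_draws = 100, seed = 7)
#> <psa_result: 100 draws, seed 7>
#>   mean incremental cost     1458.20
#>   mean incremental QALYs    0.09818
#>   P(cost-effective at 20,000/QALY) = 0.650

nnt_10yr(0.10, p$effect, p$profile)$nnt
#> [1] 56
```

Treating this synthetic 60-year-old male cohort at 10% risk costs an extra
£1487 and gains 0.100 QALYs per person over a lifetime — £14 880 per QALY,
cost-effective at the £20 000 threshold. Treatment stops being
cost-effective below a 10-year risk of about 7.4%, and about 56 such men
must be treated for 10 years to avoid one CVD event.

A command-line wrapper with the same functionality is installed at
`inst/cli/htnce` (subcommands `simulate`, `compare`, `psa`, `threshold`,
`scenarios`, `make-fixtures`).

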