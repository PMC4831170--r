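---
title: "A Markov cohort cost-utility model for anti-VEGF treatment of diabetic macular edema"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-utility model for anti-VEGF treatment of diabetic macular edema}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(dmecea)
```

## The decision problem

Visual impairment from diabetic macular edema (DME) is treated with
intravitreal anti-VEGF injections. From a third-party payer's point of view
the question is which regimen — ranibizumab 0.5 mg as needed (PRN),
ranibizumab 0.5 mg treat-and-extend (T&E), or aflibercept 2 mg every 8 weeks
after five loading doses (2q8) — buys the most health for the money spent.
`dmecea` answers this with a cohort state-transition (Markov) model: a
hypothetical cohort of DME patients is advanced through health states
defined by visual acuity, and each strategy's lifetime discounted costs,
quality-adjusted life years (QALYs) and years without visual impairment are
accumulated and compared.

## Model structure

**States.** Best corrected visual acuity (BCVA) on the ETDRS letter scale
(0–100) is cut into eight contiguous bands of two chart lines (10 letters),
plus one absorbing death state. Two lines is the conventional threshold for
a clinically significant change, so a band is the smallest clinically
meaningful unit of movement. The default edges
`{25, 35, 45, 55, 65, 75, 85}` place one boundary exactly at the
visual-impairment threshold (35 letters, inclusive): the model's "years
without visual impairment" is time spent alive above 35 letters. The edge
set is configurable; the published sources fix neither the edges nor
whether the top band is open, so the default is our choice, anchored to the
one boundary that is pinned down (the impairment threshold).

**Cycles and horizon.** The cohort moves once per 3-month cycle
(`cycle_years = 0.25`), entering at age 63 with the baseline distribution
spread over the trial recruitment window (39–78 letters). "Lifetime" means
until the cohort reaches the life-table cap, age 100 by default — 148
cycles from age 63.

**Transitions.** Each cycle the occupancy vector is multiplied by the
period's transition matrix. Treatment-year matrices (years 1–3) are biased
toward improvement; from year 4 the cohort follows untreated natural
history, biased toward decline. Death competes multiplicatively: clinical
probabilities are scaled by the cycle's survival probability and the
remainder goes to the death column. We chose this multiplicative
composition over subtracting the death probability from the diagonal
because it can never produce negative probabilities and keeps rows summing
to one by construction.

**Mortality.** Annual all-cause mortality is looked up at the cohort's
floored age, converted to a hazard, multiplied by the combined
disease-related relative risk — 1.27 (diabetes) × 1.93 (DME) = 2.4511,
conventionally quoted as 2.45 — and converted back to a per-cycle
probability. Scaling the hazard rather than the probability keeps the
result below one for any relative risk. The relative risk is applied for
life, including the natural-history phase; whether it should attenuate
after treatment is unknowable from the sources, and keeping it constant
affects all arms equally.

## Relative efficacy between arms

Only the PRN arm's transitions are treated as directly observed. The
comparator arms derive from them through odds ratios on *improving* (moving
to any better band):

* aflibercept year 1 = PRN pushed through the **inverse** of OR 1.5949
  (ranibizumab PRN vs aflibercept, months 0–3);
* T&E year 1 = the derived aflibercept matrix pushed **forward** through
  OR 1.65 (T&E vs aflibercept, months 0–3).

For a row with aggregate improvement probability $p$, the adjusted
probability is $p' = \mathrm{OR}\,p/(1-p+\mathrm{OR}\,p)$; mass inside the
improvement set is rescaled by $p'/p$ and mass outside by $(1-p')/(1-p)$.
This keeps rows stochastic, is the identity at OR = 1, and round-trips
exactly under the inverse odds ratio. Because the published odds ratios are
labelled "month 0–3", they modify the first model cycle only by default
(`or_cycles`); years 2–3 reuse the PRN matrices in every arm. Which
transitions an aggregate odds ratio should modify is genuinely open; acting
on the aggregate odds of any improvement with proportional rescaling is the
least-committal choice that preserves row structure.

## Economic accumulation

**Discounting.** Costs and outcomes beyond the first year are discounted at
3.5% per year. The factor is 1 through year 1 and $(1+r)^{-t}$ afterwards
with $t$ measured from model entry; measuring from the end of year 1
instead is a configuration switch (`from_time_zero = FALSE`). Rates 0% and
7% are the conventional sensitivity bounds.

**Half-cycle correction.** Payoffs for cycle $t$ are carried by the average
of the occupancy at the cycle's start and end (a trapezoid), valued at the
cycle midpoint's discount factor. The same correction applies to costs,
QALYs and the impairment-free time indicator. The trapezoidal total
provably lies between the start-of-cycle and end-of-cycle accumulations,
which the tests assert on random scenarios.

**Utilities.** Utilities differ by whether the treated eye is the
better-seeing (BSE) or worse-seeing (WSE) eye: 40.2% of patients are
BSE-treated, 59.6% WSE-treated, and the 22% with bilateral disease take BSE
values. The effective BSE weight is
$0.22 + 0.78 \times 0.402/(0.402+0.596)$; the unilateral shares are
renormalised because they are published as 0.402 and 0.596 (summing to
0.998). Death has utility 0.

**Costs** (payer perspective, EUR, 2014 tariffs): drug acquisition at the
reimbursed price per injection, administration €66.40 per injection,
monitoring €10 per visit, laser €118 per session (62.5% × €177 hospital +
37.5% × €20.15 outpatient), and an annual state cost for bands at or below
35 letters (€5248.49 in year 1, €4866.49 from year 2), charged per cycle as
a quarter of the annual rate. The state cost is treated as all-in — it
subsumes the €4344 annual blindness allowance to avoid double counting;
`add_blindness_allowance = TRUE` adds the allowance on top for the worst
band, for analyses that treat it as a separate payment rather than a
transfer. Treatment components stop after the 3 treatment years; state
costs continue for life.

Two published inconsistencies are taken at face value rather than
"corrected": the reimbursed prices (€656.16 ranibizumab, €613.36
aflibercept) are not reproducible as list price × (1 − stated rebate), so
strategies carry an explicit resolved `price` used by the model while list
price and rebate are kept for audit; and the outpatient laser tariff is
used as the printed €20.15.

**Incremental results.** For each strategy versus aflibercept the model
reports Δcost, ΔQALY, Δyears without impairment, the ICER (labelled
"dominant"/"dominated" when the increments disagree in sign, with the raw
ratio kept for audit), and the net monetary benefit
$\mathrm{NMB} = \Delta\mathrm{QALY} \times \lambda - \Delta\mathrm{cost}$
at the willingness-to-pay threshold λ = €25,000/QALY.

## What the synthetic generator stands in for

The year-by-year transition matrices, the per-band utilities (from a NICE
appraisal), and the per-year injection counts are not printed in the public
sources. The generator replaces them with internally consistent stand-ins,
all driven by one scenario seed:

* **Transition matrices** are banded random walks: moves of 0, ±1, ±2 bands
  with base weights 0.55/0.18/0.045, multiplicative log-normal jitter
  (sd 0.02), and a bias that scales upward moves by $1+b$ and downward by
  $1-b$. Treatment years use $b = 0.25, 0.10, 0.10$; natural history uses
  $b = -0.10$ — improvement concentrated in year 1, decline thereafter,
  with per-quarter jumps beyond two bands excluded as clinically
  implausible.
* **Utilities** interpolate linearly between anchors: BSE 0.50–0.85 (wide —
  vision in the better eye drives function), WSE 0.70–0.80 (narrow).
  Monotone in band by construction.
* **Life table** is Gompertz, $p(a) = 1-\exp(-5\times10^{-5} e^{0.09a})$,
  capped at 1 at age 100 — about 1.4% annual mortality at 63, a plausible
  general-population level.
* **Injection/monitoring schedules** are clinically plausible placeholders
  (e.g. aflibercept year 1 encoded as 3/2/1.5/1.5 injections per quarter:
  five loading doses then every 8 weeks); the sources themselves note that
  injection-count practice varies.

Real values drop in via the scenario file and bypass the generator
entirely. Because these stand-ins are synthetic, the model reproduces the
published analysis *qualitatively* — both ranibizumab regimens come out
cost-saving with small QALY gains, hence dominant, with positive NMB, and
the tornado is led by the two drug prices and the months 0–3 odds ratio —
but the absolute cost and QALY levels are not expected to match the
published table, and passing tests show correctness of the machinery, not
agreement with the unavailable inputs.

## Sensitivity analyses

**One-way (tornado).** Each parameter in the ranges table is set to its low
and high value with everything else at base and the full pipeline is rerun;
rows are sorted by NMB swing. Parameters are addressed by scenario path, so
any numeric field is variable; the ranibizumab price path deliberately hits
both arms that share the drug. The published horizon row is ambiguous in
our source text, so the default range runs from 3 years to lifetime.

**Probabilistic (PSA).** Second-order Monte Carlo with distributions chosen
by parameter nature: gamma for costs and prices (mean at base, the one-way
range as a 95% interval), log-normal for odds ratios and the mortality
relative risk (the one-way range as a 95% interval — the published table
lists "standard error" without printing one), beta for per-band utilities
(effective sample size 100), and Dirichlet for the observed arm's
transition rows (concentration = 100 × base row), drawn jointly so rows
stay stochastic and structural zeros stay zero. Beta draws are sorted
within each eye class to preserve band monotonicity. Comparator matrices
are re-derived each draw from the drawn PRN matrices and drawn odds ratios,
so parameter uncertainty propagates through the derivation chain. Defaults:
1000 draws, seed 20140801; a zero-variance switch makes every draw
reproduce the base case exactly, which the tests assert. The
cost-effectiveness acceptability curve reports, at each willingness-to-pay
value, the fraction of draws with positive NMB.

**Break-even price.** Bisection on a strategy's reimbursed price until its
NMB versus the reference crosses zero (bracket width €0.01). NMB is
strictly decreasing in the strategy's own price, so the root is unique; the
search refuses brackets without a sign change and reports the NMB at both
ends.

## Numerical choices and degenerate inputs

* Row-stochasticity is enforced within 1e−9; occupancy conservation is
  asserted at the same tolerance.
* An annual death probability of 1 maps to a cycle probability of 1
  directly (the hazard is infinite; no NaN).
* Odds-ratio adjustment of a row with zero improvement mass is the
  identity; a row entirely inside the improvement set is returned unchanged
  with a warning.
* A zero QALY difference yields an "undefined" ICER label; the NMB is still
  computed.
* Utility multipliers (sensitivity analysis) cap the product at 1 — a
  utility above full health is not meaningful.
* The engine's correctness is cross-checked against an individual-level
  microsimulation of 100,000 patients on a 4-state, 20-cycle instance
  (agreement within 3 standard errors per state per cycle); the
  microsimulation lives in the test suite only, never as the engine.

## Problem sizes

The base case runs 148 cycles × 9 states × 3 strategies and takes well
under a second. The test suite exercises 100 generator seeds for engine
validation, 100,000 microsimulated patients for the oracle comparison, and
a 1000-draw zero-variance PSA; the acceptance workflow runs the full
1000-draw PSA and two bisection searches. These sizes make every analysis
exact enough for its purpose while keeping a full run in tens of seconds.

## Known limitations

* Absolute results depend on the synthetic stand-ins; only the published
  unit inputs and the qualitative structure of the conclusions are
  reproducible from public numbers.
* No adverse-event states (excluded from the underlying model design), no
  tunnel states, no indirect or societal costs, no multi-way efficiency
  frontier (comparisons are pairwise against aflibercept), and no expected
  value of perfect information.
* Bilateral patients are folded into the BSE utility class by a fixed
  share; no per-eye cost doubling is modelled, mirroring the underlying
  model's treatment of bilaterality as a utility assumption.

## A worked example

```{r example, eval = FALSE}
scenario <- dme_scenario()        # default study conditions, seed 42
res <- run_cea(scenario)
res$strategies                    # discounted cost / QALYs / years no VI
tidy(res)                         # increments, ICER or dominance, NMB

ow <- run_owsa(scenario)          # tornado table
psa <- run_psa(scenario)          # 1000 draws
ceac <- build_ceac(psa)
find_price_threshold(scenario, "ranibizumab_prn")
```
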