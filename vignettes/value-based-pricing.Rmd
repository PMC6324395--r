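---
title: "Value-based pricing of epinephrine autoinjector prescriptions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Value-based pricing of epinephrine autoinjector prescriptions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epivalue)
```

## The decision problem

Personal epinephrine autoinjectors are the standard of preparedness for
children with peanut allergy, yet US twin-pack prices have ranged above
$700 per year for a device whose marginal production cost is a few
dollars. `epivalue` asks the value-based pricing question: *at what annual
twin-pack price does a personal prescription become cost-effective, given
what it actually buys — a reduction in the (very small) risk of a fatal
food-allergic reaction?*

The package compares two strategies for a birth cohort with peanut
allergy over an 80-year horizon:

* **prescribed** — an annual personal autoinjector prescription (two twin
  packs per year below age 19, one from 19 on), with a probability
  `p_carry = 0.67` that the device is actually available and used at the
  moment of anaphylaxis;
* **not prescribed** — no personal device; emergency care is reached
  without one.

## Model structure

The model is an annual-cycle Markov state-transition model with four
states: **allergic**, **tolerant** (permanent, reached by spontaneous
resolution), and two absorbing death states, **background death** and
**food-allergy death**. Both a deterministic cohort-expectation solver
(`run_cohort()`) and a patient-level microsimulation (`run_microsim()`)
evaluate the same cycle plans, so the microsimulation means converge to
the cohort values; the cohort solver is the noise-free analogue used
wherever determinism matters (price solving, DSA, PSA default).

Per cycle at age $a$, a patient in the allergic state faces competing
exits, combined additively:

* food-allergy death with probability $h(a)\,m$, where $h(a)$ is the
  annual food-allergy fatality rate among allergic persons
  ($3.25\times10^{-6}$ below age 20, $1.81\times10^{-6}$ from age 20) and
  $m$ the availability multiplier: $m = rr$ without a prescription
  (base $rr = 10$) and $m = p_c + (1-p_c)\,rr$ with one (the carriage
  mixture, $0.67 + 0.33\cdot 10 = 3.97$ at base case). In the
  microsimulation, carriage is instead drawn as an independent Bernoulli
  per at-risk cycle — same expectation, per-event realization;
* background death with the life-table probability $q_x$;
* spontaneous resolution, only in the cycle where age equals
  `resolution_age` (4), applied to the remainder after death exits:
  $p_{res}\,(1 - h(a)m - q_x)$ with $p_{res} = 0.22$.

The fatality hazard is modelled as an annual rate among the allergic —
not as a per-reaction conditional probability — because the published
rates are per person-year in the food-allergic population; this
formulation also reproduces the published ratio of arm fatality risks
(our prescribed/no-prescription ratio is $3.97/10 = 0.397$).

### Accounting

* **Costs** (2018 USD). While allergic: the annual device purchase
  (prescribed arm only; no refund on mid-cycle death — prescriptions are
  annual) plus the expected emergency pathway
  $p_{ED}(c_{ED} + p_{hosp}\,c_{hosp}) = 0.01\,(691 + 0.35 \cdot 5899)
  \approx \$27.56$/year. A food-allergy death cycle additionally accrues
  one ED visit plus the expected hospitalization cost *in both arms
  identically*, so pre-hospital fatality costs cannot bias the
  incremental comparison. The 7%/year symptomatic-exposure rate
  (`p_reaction`) carries no cost or utility consequence beyond the
  1%/year ED pathway; it is retained as a parameter and tornado axis but
  is computationally inert in the base model.
* **QALYs.** Utility 1 while tolerant, $1 - 0.09$ while allergic, 0 when
  dead. Half-cycle correction is trapezoidal occupancy weighting: each
  cycle contributes the mean of its start- and end-of-cycle utility (a
  patient dying in a cycle contributes half a cycle at their living
  weight). With full survival, no decrement and no discounting, 80
  cycles yield exactly 80 QALYs.
* **Discounting.** Cycle $t$ is discounted by $(1+r)^{-t}$ with
  $r = 0.03$ for both costs and QALYs; accruals are not sub-annually
  discounted.

### Economics

`compare_arms()` forms $\Delta C$, $\Delta Q$, the ICER
$\Delta C / \Delta Q$, and net monetary benefit
$\mathrm{NMB} = \lambda \Delta Q - \Delta C$ at a willingness-to-pay
threshold $\lambda$ (default \$100 000/QALY), with dominance handling and
a $|\Delta Q| < 10^{-9}$ guard under which no ICER is formed
(microsimulation noise protection).

`solve_price_ceiling()` exploits the structure of the model: only the
prescribed arm buys devices, so $\Delta Q$ is price-invariant and
$\Delta C$ is affine in price — the NMB is linear and strictly decreasing
in price and the ceiling (the price at which the ICER equals $\lambda$)
is a unique root. It is bracketed and bisected.

## Background mortality

All-cause mortality enters through a `life_table` object: annual death
probabilities $q_x$ for integer ages 0…`max_age`, with
$q_{\mathrm{max\_age}} = 1$ absorbing. Real tables are read from
delimited `age,qx` text (`load_life_table()`); so the package runs
self-contained, `synth_life_table()` generates a US-like schedule from a
Gompertz–Makeham hazard with an infant excess:

$$q_x = 1 - \exp\{-(a + b\,c^x + \mathrm{infant}\cdot[x=0])\}$$

The default constants ($a = 5\times10^{-4}$, $b = 3.5\times10^{-5}$,
$c = 1.095$, infant excess $5.5\times10^{-3}$, terminal age 110) are
fixed calibration values — chosen once, not fitted at runtime — giving
period life expectancy at birth of about 78.7 years, survival to 60 of
about 0.886, and first-year mortality of about 0.006, emulating recent
US all-cause mortality.

What the generator emulates: the overall level and age-shape (infant
spike, low child/young-adult plateau, senescent rise) of a sex-averaged
US period table. What it does not: the young-adult external-cause hump,
sex stratification, cohort (generational) mortality improvement, and any
secular trend. Because food-allergy fatality and device costs are
concentrated at young ages where all schedules are nearly flat and low,
results are insensitive to these refinements; tests passing on the
synthetic table therefore demonstrate correctness of the machinery and
reproduction of the published magnitudes, not calibration to any one
official table.

## Sensitivity analysis

* **Tornado (`one_way_dsa()`).** Each parameter is moved to the ends of
  its published sensitivity range with everything else at base case;
  entries are sorted by ICER spread. At the \$715 price no range end
  brings the ICER below \$100 000/QALY.
* **PSA (`run_psa()`).** Joint independent draws: lognormal fatality
  rates matched on the log scale to their published 95% CIs; gamma costs
  moment-matched to theirs; uniform draws over the published sensitivity
  ranges for the probabilities and the utility decrement, which have no
  printed CIs (a beta family is available for inputs that do). The
  structural dials `rr_no_epi`, `discount_rate`, `start_age` and
  `resolution_age` are deliberately *not* sampled by default — they are
  assumption scenarios, not sampling uncertainty — but remain tornado
  axes and can be added as distributions. Each trial is evaluated in
  cohort mode by default (parameter uncertainty only); a
  microsimulation-per-trial engine exists behind `engine = "microsim"`.
  Invalid joint draws are redrawn, with a documented cap (default 100)
  before erroring.

## Numerical choices

* Transition rows must sum to 1 within $10^{-12}$; a negative remainder
  (hazards summing above 1, impossible at published magnitudes) is an
  error, not a silent clamp.
* The bisection root is located to $10^{-6}$ USD (well under 60
  iterations) so the reported ICER at the ceiling matches the threshold
  to a relative $10^{-4}$; the ceiling *price* is reported at cent
  precision. Resolving the price only to \$0.01 would leave the ICER
  ~\$40/QALY off the threshold, since near the base-case ceiling the
  ICER moves ≈\$4 000/QALY per \$1 of price.
* Age boundaries are deliberately distinct: pack count drops at 19
  (supply convention) while the adult fatality rate begins at 20 (the
  pediatric rate covers ages 0–19). The cohort starts at birth, so the
  pediatric rate is applied from age 0.
* The solved ceiling is a price per twin pack per year, children buying
  two packs and adults one — consistent with the published per-year cost
  scaling.
* Microsimulation RNG: one seeded stream, drawn cycle-by-cycle across
  the patient vector in a fixed documented order; results are
  bit-reproducible given `(seed, n_patients)`, and the caller's RNG
  state is restored on exit. PSA trial draws (and per-trial
  microsimulation seeds, if used) derive from the single PSA seed.

## Problem sizes

The published analysis simulates 100 000 patients per arm and 1000 PSA
trials; the package defaults and its acceptance checks use the same
sizes (a full microsimulation arm runs in about a second; a 1000-trial
cohort-mode PSA in about twelve). Unit and property tests use smaller
cohorts (2 000–20 000 patients) where only estimator consistency, not
published magnitudes, is at stake.

## Worked base case

```{r base-case, eval = FALSE}
params <- model_params()
table <- synth_life_table()

ce <- compare_arms(run_cohort(params, table, "prescribed"),
                   run_cohort(params, table, "not_prescribed"),
                   wtp = 1e5)
ce$icer            # ~ $2.95M per QALY at $715: not cost-effective

solve_price_ceiling(params, table, wtp = 1e5)$ceiling_price  # ~ $24
run_scenario_suite(params, table)   # ceilings for every named scenario
```

## Known limitations

* The health-state structure (four states, hazard-formulated fatality)
  is a reconstruction from the published description; per-reaction
  severity branches, if the original used them, are absorbed into the
  annual hazard. The reconstruction reproduces the published arm
  fatality ratio, costs, ICERs and ceiling prices within their
  uncertainty, but individual microsimulation realizations of the rare
  fatality outcome at $n = 100\,000$ carry ~9–14% relative standard
  error.
* Carriage has no persistence model (each at-risk cycle is an
  independent Bernoulli), adverse events from incorrect epinephrine use
  are excluded, and costs of living with the allergy other than
  devices/ED/hospitalization are invariant between arms and omitted.
* Parameters are sampled independently in the PSA; no correlation
  structure is available to inform anything richer.
* All costs are 2018 USD as published; there is no inflation machinery.
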