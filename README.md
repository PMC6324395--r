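# epivalue

Cost-effectiveness and value-based pricing of personal epinephrine
autoinjector prescriptions for children with peanut allergy.

US epinephrine twin packs have sold for more than $700 per year. For a
child with peanut allergy, what that annual prescription buys — beyond
reassurance — is a reduction in the already-small risk of a fatal
food-allergic reaction. `epivalue` is for health-economics researchers
and policy analysts who want to quantify that trade-off: it prices the
device from its outcomes rather than its market.

## The model

An annual-cycle Markov state-transition model follows a birth cohort
with peanut allergy for 80 years through four states — *allergic*,
*tolerant* (22% resolve spontaneously at age 4), and two absorbing death
states (background mortality from a life table; food-allergy death).
While allergic, the annual food-allergy fatality rate h(a)
(3.25 per million person-years below age 20, 1.81 per million from 20)
is scaled by device availability:

* no prescription: h(a) · rr, with rr = 10 (sensitivity to 100);
* prescription: h(a) · (p_c + (1 − p_c) · rr), the carriage mixture
  with p_c = 0.67.

Costs (2018 USD: $715 per twin pack, two packs/year under age 19 and one
after; ED visit $691; hospitalization $5 899 after 35% of the 1%/year ED
visits) and QALYs (utility decrement 0.09 while allergic) are discounted
at 3%/year with half-cycle correction. Strategies are compared by the
incremental cost-effectiveness ratio ICER = ΔC/ΔQ and net monetary
benefit at a willingness-to-pay threshold λ = $100 000/QALY, and the
**value-based ceiling price** is the twin-pack price at which
ICER(price) = λ, found by bisection (ΔQ is price-invariant, so the root
is unique).

Both a deterministic cohort-expectation solver and a patient-level
microsimulation (100 000 patients/arm, reproducible by seed) evaluate
the same cycle plans; tornado-style one-way sensitivity analysis and
probabilistic sensitivity analysis (1000 trials, CEAC output) cover the
published uncertainty ranges. Background mortality comes from a
calibrated Gompertz–Makeham synthetic US-like life table (life
expectancy ≈ 78.7 y) or any user-supplied `age,qx` file.

## Worked example

```r
library(epivalue)
params <- model_params()          # published base-case inputs
table  <- synth_life_table()      # US-like background mortality

rx   <- run_cohort(params, table, "prescribed")
norx <- run_cohort(params, table, "not_prescribed")
compare_arms(rx, norx, wtp = 1e5)
#> <ce_result>
#>   delta cost  $26 289.28
#>   delta QALY  0.008897
#>   ICER        $2 954 855 per QALY
#>   NMB @ $100 000/QALY: $-25 399.58 (not_cost_effective)

solve_price_ceiling(params, table, wtp = 1e5)
#> <price_solve_result> base_case: ceiling $24.22 per twin pack (ICER $100 000 at wtp $100 000)

run_microsim(params, table, "not_prescribed", 1e5, seed = 42)
#> <arm_result> not_prescribed (microsim)
#>   mean cost   $672  (95% CI 662-681)
#>   mean QALYs  27.6387  (95% CI 27.6159-27.6615)
#>   fatality    0.00153  (95% CI 0.001288-0.001772)
```

Read: at $715 per twin pack the prescription strategy costs an extra
~$26 000 per patient over a lifetime and buys ~0.009 discounted QALYs
(the monetized value of the averted fatality risk), an ICER near $3M per
QALY — far above any conventional threshold. Bisecting the price finds
the prescription becomes cost-effective at $100 000/QALY only when a
twin pack costs about $24. The microsimulation line shows the
individual-level engine: about 1.5 food-allergy deaths per 1 000
unprescribed patients over 80 years, with its Monte-Carlo interval.

Named scenarios (100-fold risk multiplier, perfect carriage, doubled
hospitalization without a device, 10-fold fatality rates, and
combinations) are built in:

```r
run_scenario_suite(params, table)       # ceiling price + ICER@$715 per scenario
one_way_dsa(params, table)              # tornado table
run_psa(params, table, seed = 1)        # 1000-trial PSA + CEAC
```

A thin command-line wrapper over the same functions ships in
`inst/cli/epival.R` (`run`, `solve-price`, `dsa`, `psa`, `sweep-price`
subcommands; TSV outputs plus a JSON run manifest).

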