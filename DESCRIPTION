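Package: epivalue
Title: Cost-Effectiveness and Value-Based Pricing of Epinephrine
    Autoinjector Prescriptions for Peanut Allergy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markov state-transition model of a birth cohort with peanut
    allergy, comparing annual personal epinephrine autoinjector
    prescriptions against no prescription over an 80-year horizon.
    Provides a deterministic cohort-expectation solver and a
    patient-level microsimulation with annual cycles, half-cycle
    correction and 3% discounting; incremental cost-effectiveness
    (ICER, net monetary benefit) at a willingness-to-pay threshold;
    one-way deterministic (tornado) and probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves; and a
    bisection solver for the value-based ceiling price of a twin-pack
    prescription. Background mortality comes from a user-supplied life
    table or a calibrated Gompertz-Makeham synthetic generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
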