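# Shared fixtures: built in code, no stored data.

# Default synthetic life table, built once per test run.
fixture_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- synth_life_table()
    tab
  }
})

# Flat-hazard life table: constant annual death probability qb below the
# terminal age. Useful for closed-form oracles.
constant_table <- function(qb, max_age = 200) {
  life_table(c(rep(qb, max_age), 1))
}

# Immortal background population (qx = 0 below the terminal age).
immortal_table <- function(max_age = 120) constant_table(0, max_age)

# Parameters stripped to a single constant fatality hazard: no resolution,
# no discounting, no costs beyond the device, equal child/adult rates.
constant_hazard_params <- function(qf, horizon = 60) {
  model_params(fatality_rate_child = qf, fatality_rate_adult = qf,
               rr_no_epi = 1, p_resolution = 0, discount_rate = 0,
               horizon = horizon)
}

expect_valid_params <- function(p) expect_silent(validate_params(p))
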