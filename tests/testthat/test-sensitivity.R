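test_that("tornado entries bracket the base case and sort by spread", {
  p <- model_params()
  lt <- fixture_table()
  base_icer <- icer_at_price(p, lt, p$price_twin_pack)$icer
  tor <- one_way_dsa(p, lt,
                     ranges = list(price_twin_pack = c(30, 715),
                                   p_carry = c(0.40, 1.00),
                                   rr_no_epi = c(10, 10)))
  expect_identical(tor$param[1:2], c("p_carry", "price_twin_pack"))
  price_row <- tor[tor$param == "price_twin_pack", ]
  expect_lt(price_row$icer_at_low, base_icer)
  expect_gte(price_row$icer_at_high, base_icer)
  # a degenerate range has zero spread
  expect_equal(tor$spread[tor$param == "rr_no_epi"], 0)
  expect_true(all(diff(tor$spread) <= 0))
})

test_that("no default range crosses the threshold at the published price", {
  tor <- one_way_dsa(model_params(), fixture_table(), wtp = 1e5)
  expect_setequal(tor$param, names(default_sensitivity_ranges()))
  expect_false(any(tor$crosses_wtp))
  expect_true(all(pmin(tor$icer_at_low, tor$icer_at_high) > 1e5))
})

test_that("ranges outside a parameter's validity domain are rejected", {
  expect_error(one_way_dsa(model_params(), fixture_table(),
                           ranges = list(p_carry = c(0.5, 1.5))),
               "p_carry")
  expect_error(one_way_dsa(model_params(), fixture_table(),
                           ranges = list(p_carry = c(1, 0.5))),
               "low <= high")
})

test_that("distribution samplers respect the parameter invariants", {
  set.seed(19)
  d <- default_param_distributions()
  for (dist in d) {
    x <- dist$sample(500)
    expect_true(all(is.finite(x)))
    expect_true(all(x >= 0))
    if (dist$param_name %in% c("p_reaction", "p_ed_visit", "p_carry",
                               "p_hospitalization", "p_resolution",
                               "utility_decrement"))
      expect_true(all(x <= 1))
  }
  # moment matching: gamma mean and CI reproduce the inputs approximately
  price <- d$price_twin_pack$sample(2e4)
  expect_equal(mean(price), 715, tolerance = 0.005)
  expect_equal(unname(quantile(price, c(0.025, 0.975))), c(685, 743),
               tolerance = 0.005)
  # lognormal CI matching for the child fatality rate
  fat <- d$fatality_rate_child$sample(2e4)
  expect_equal(unname(quantile(fat, c(0.025, 0.975))),
               c(1.73e-6, 6.10e-6), tolerance = 0.05)
  # every joint draw validates
  for (i in 1:50)
    expect_valid_params(
      epivalue:::sample_param_set(model_params(), d))
})

test_that("a point-mass PSA reproduces the deterministic comparison", {
  p <- model_params()
  lt <- fixture_table()
  pts <- list(param_distribution("p_carry", "point", value = p$p_carry),
              param_distribution("price_twin_pack", "point",
                                 value = p$price_twin_pack))
  psa <- run_psa(p, lt, distributions = pts, n_trials = 5, seed = 3)
  det <- icer_at_price(p, lt, p$price_twin_pack)
  expect_true(all(abs(psa$draws$delta_cost - det$delta_cost) < 1e-9))
  expect_true(all(abs(psa$draws$delta_qaly - det$delta_qaly) < 1e-12))
})

test_that("PSA draws are reproducible and the CEAC is a monotone probability", {
  p <- model_params()
  lt <- fixture_table()
  psa1 <- run_psa(p, lt, n_trials = 60, seed = 12)
  psa2 <- run_psa(p, lt, n_trials = 60, seed = 12)
  expect_identical(psa1$draws, psa2$draws)
  expect_identical(psa1$ceac, psa2$ceac)
  expect_true(all(psa1$ceac$p_cost_effective >= 0 &
                  psa1$ceac$p_cost_effective <= 1))
  if (all(psa1$draws$delta_qaly > 0))
    expect_true(all(diff(psa1$ceac$p_cost_effective) >= 0))
})

test_that("the cost-effective fraction is stable across half-samples", {
  p <- model_params()
  lt <- fixture_table()
  psa <- run_psa(p, lt, n_trials = 2000, seed = 8)
  nmb <- psa$wtp * psa$draws$delta_qaly - psa$draws$delta_cost
  halves <- split(nmb > 0, rep(1:2, each = 1000))
  expect_lt(abs(mean(halves[[1]]) - mean(halves[[2]])), 0.04)
})
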