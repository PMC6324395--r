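test_that("the effective fatality hazard follows the carriage mixture", {
  p <- model_params()
  expect_equal(effective_fatality_hazard(p, 10, "not_prescribed"), 3.25e-5)
  expect_equal(effective_fatality_hazard(p, 10, "prescribed"),
               3.25e-6 * (0.67 + 0.33 * 10))
  expect_equal(effective_fatality_hazard(p, 10, "prescribed"), 1.29025e-5)
  # adult rate from the fatality age boundary
  expect_equal(effective_fatality_hazard(p, 20, "not_prescribed"), 1.81e-5)
  expect_equal(effective_fatality_hazard(p, 19, "not_prescribed"), 3.25e-5)
  # perfect carriage collapses the multiplier to 1
  p1 <- model_params(p_carry = 1)
  expect_equal(effective_fatality_hazard(p1, 10, "prescribed"), 3.25e-6)
})

test_that("cycle costs combine device supply and the emergency pathway", {
  p <- model_params()
  expect_equal(cycle_cost(p, 10, "not_prescribed", "allergic"),
               0.01 * (691 + 0.35 * 5899))  # 27.5565
  expect_equal(cycle_cost(p, 5, "prescribed", "allergic"),
               2 * 715 + 27.5565)
  expect_equal(cycle_cost(p, 19, "prescribed", "allergic"),
               1 * 715 + 27.5565)  # single pack from the supply boundary
  expect_identical(cycle_cost(p, 30, "prescribed", "tolerant"), 0)
  expect_identical(cycle_cost(p, 30, "not_prescribed", "dead_background"), 0)
})

test_that("cycle utilities apply the allergy decrement only while allergic", {
  p <- model_params()
  expect_equal(cycle_utility(p, "allergic"), 0.91)
  expect_identical(cycle_utility(p, "tolerant"), 1)
  expect_identical(cycle_utility(p, "dead_food_allergy"), 0)
  expect_equal(cycle_utility(model_params(utility_decrement = 0),
                             "allergic"), 1)
})

test_that("cycle plans conserve probability for random valid inputs", {
  lt <- fixture_table()
  set.seed(11)
  for (i in 1:1000) {
    p <- model_params(
      fatality_rate_child = runif(1, 0, 1e-3),
      fatality_rate_adult = runif(1, 0, 1e-3),
      rr_no_epi = runif(1, 1, 100),
      p_carry = runif(1),
      p_resolution = runif(1),
      resolution_age = sample(0:30, 1),
      discount_rate = runif(1, 0, 0.1))
    age <- sample(0:79, 1)
    strat <- sample(STRATEGIES, 1)
    plan <- build_cycle_plan(p, lt, age, strat)
    expect_lt(abs(sum(plan$from_allergic) - 1), 1e-12)
    expect_lt(abs(sum(plan$from_tolerant) - 1), 1e-12)
    expect_true(all(plan$from_allergic >= 0))
    expect_true(plan$discount_factor > 0 && plan$discount_factor <= 1)
  }
})

test_that("resolution applies once, to the remainder after death exits", {
  p <- model_params()
  lt <- fixture_table()
  plan4 <- build_cycle_plan(p, lt, 4, "not_prescribed")
  pf <- effective_fatality_hazard(p, 4, "not_prescribed")
  qb <- annual_mortality(lt, 4)
  expect_equal(plan4$from_allergic[["to_tolerant"]],
               0.22 * (1 - pf - qb))
  expect_identical(build_cycle_plan(p, lt, 5, "not_prescribed")
                   $from_allergic[["to_tolerant"]], 0)
})

test_that("degenerate full-survival cohort accrues exactly 80 QALYs", {
  p <- model_params(fatality_rate_child = 0, fatality_rate_adult = 0,
                    p_resolution = 0, utility_decrement = 0,
                    discount_rate = 0)
  res <- run_cohort(p, immortal_table(), "not_prescribed")
  expect_equal(res$mean_qaly, 80, tolerance = 1e-12)
  expect_identical(res$p_fatality, 0)
})

test_that("occupancy is conserved to 1e-12 every cycle", {
  lt <- fixture_table()
  for (strat in STRATEGIES) {
    res <- run_cohort(model_params(), lt, strat, keep_trace = TRUE)
    sums <- rowSums(res$trace)
    expect_true(all(abs(sums - 1) <= 1e-12))
  }
})

test_that("constant-hazard lifetime fatality matches the closed form", {
  qf <- 2e-4
  qb <- 0.01
  Tn <- 60
  p <- constant_hazard_params(qf, horizon = Tn)
  res <- run_cohort(p, constant_table(qb), "not_prescribed")
  closed <- qf / (qf + qb) * (1 - (1 - qf - qb)^Tn)
  expect_lt(abs(res$p_fatality - closed), 1e-6)
  # both strategies coincide when rr_no_epi = 1
  expect_equal(run_cohort(p, constant_table(qb), "prescribed")$p_fatality,
               res$p_fatality)
})

test_that("microsimulation is reproducible given its seed", {
  p <- model_params()
  lt <- fixture_table()
  a <- run_microsim(p, lt, "prescribed", 2000, seed = 9)
  b <- run_microsim(p, lt, "prescribed", 2000, seed = 9)
  expect_identical(a, b)
  c <- run_microsim(p, lt, "prescribed", 2000, seed = 10)
  expect_false(identical(a$mean_cost, c$mean_cost))
  # the caller's RNG stream is left untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(run_microsim(p, lt, "prescribed", 100, seed = 4))
  expect_identical(runif(1), before)
})

test_that("microsimulation means agree with cohort expectations", {
  p <- model_params()
  lt <- fixture_table()
  for (strat in STRATEGIES) {
    coh <- run_cohort(p, lt, strat)
    mic <- run_microsim(p, lt, strat, 2e4, seed = 31)
    se <- function(ci) (ci[2] - ci[1]) / (2 * qnorm(0.975))
    expect_lt(abs(mic$mean_cost - coh$mean_cost), 3 * se(mic$ci_cost))
    expect_lt(abs(mic$mean_qaly - coh$mean_qaly), 3 * se(mic$ci_qaly))
    expect_lt(abs(mic$p_fatality - coh$p_fatality),
              3 * max(se(mic$ci_fatality), 1e-12))
  }
})

test_that("microsimulation error shrinks as n^(-1/2)", {
  p <- model_params()
  lt <- fixture_table()
  expected <- run_cohort(p, lt, "not_prescribed")$p_fatality
  ns <- c(1e3, 1e4, 1e5)
  seeds <- 1:8
  mae <- vapply(ns, function(n) {
    errs <- vapply(seeds, function(s)
      abs(run_microsim(p, lt, "not_prescribed", n, seed = s)$p_fatality -
            expected), 0)
    mean(errs)
  }, 0)
  slope <- coef(lm(log10(mae) ~ log10(ns)))[2]
  expect_lt(abs(slope - (-0.5)), 0.2)
})

test_that("risk and price monotonicity hold across the engines", {
  lt <- fixture_table()
  # increasing rr_no_epi never decreases the unprescribed fatality risk
  pf <- vapply(c(1, 5, 10, 50, 100), function(rr)
    run_cohort(model_params(rr_no_epi = rr), lt,
               "not_prescribed")$p_fatality, 0)
  expect_true(all(diff(pf) >= 0))
  # price changes never touch QALYs; prescribed cost strictly increases
  runs <- lapply(c(30, 300, 715), function(pr)
    run_cohort(model_params(price_twin_pack = pr), lt, "prescribed"))
  qalys <- vapply(runs, `[[`, 0, "mean_qaly")
  costs <- vapply(runs, `[[`, 0, "mean_cost")
  expect_equal(qalys[1], qalys[2])
  expect_equal(qalys[2], qalys[3])
  expect_true(all(diff(costs) > 0))
})

test_that("universal resolution at birth stops all later drug spending", {
  p <- model_params(p_resolution = 1, resolution_age = 0, start_age = 0)
  lt <- fixture_table()
  full <- run_cohort(p, lt, "prescribed")
  first_cycle_only <- run_cohort(model_params(p_resolution = 1,
                                              resolution_age = 0,
                                              horizon = 1), lt, "prescribed")
  expect_equal(full$mean_cost, first_cycle_only$mean_cost)
})

test_that("null-effect arms differ by less than three pooled standard errors", {
  p <- model_params(rr_no_epi = 1)
  lt <- fixture_table()
  m1 <- run_microsim(p, lt, "prescribed", 2e4, seed = 51)
  m0 <- run_microsim(p, lt, "not_prescribed", 2e4, seed = 52)
  pooled_se <- sqrt(m1$p_fatality * (1 - m1$p_fatality) / m1$n_patients +
                    m0$p_fatality * (1 - m0$p_fatality) / m0$n_patients)
  expect_lt(abs(m1$p_fatality - m0$p_fatality),
            3 * max(pooled_se, 1 / m1$n_patients))
})
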