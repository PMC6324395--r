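# Markov engine: annual-cycle state-transition model over the states
# ALLERGIC, TOLERANT, DEAD_BACKGROUND, DEAD_FOOD_ALLERGY, evaluated either
# as a deterministic cohort expectation or as a patient-level
# microsimulation. Both share the same cycle accounting:
#   * drug cost accrues to patients alive and allergic at cycle start;
#   * the ED pathway (visit, then possible admission) accrues to the same
#     at-risk set;
#   * a food-allergy death cycle additionally accrues one ED visit plus the
#     expected hospitalization cost, identically in both arms;
#   * QALYs use trapezoidal (half-cycle) occupancy weighting: each cycle
#     contributes the mean of its start- and end-of-cycle utility;
#   * cycle t is discounted by (1 + r)^(-t).

#' Model health states and strategies
#'
#' The model's four health states and two strategy arms, as character
#' constants. \code{DEAD_*} states are absorbing and tolerance is permanent.
#'
#' @format Character vectors.
#' @export
HEALTH_STATES <- c("allergic", "tolerant", "dead_background",
                   "dead_food_allergy")

#' @rdname HEALTH_STATES
#' @export
STRATEGIES <- c("prescribed", "not_prescribed")

match_strategy <- function(strategy)
  match.arg(strategy, STRATEGIES)

base_fatality_rate <- function(params, age) {
  ifelse(age < params$adult_age_fatality,
         params$fatality_rate_child, params$fatality_rate_adult)
}

#' Effective annual food-allergy fatality hazard
#'
#' The age-specific background food-allergy fatality rate scaled by device
#' availability. Without a prescription the full risk multiplier
#' \code{rr_no_epi} applies; with one, the multiplier is the carriage
#' mixture \eqn{p_{carry} \cdot 1 + (1 - p_{carry}) \cdot rr}.
#'
#' @param params \code{model_params}.
#' @param age age in years (vectorized).
#' @param strategy \code{"prescribed"} or \code{"not_prescribed"}.
#' @return Annual fatality probability.
#' @export
#' @examples
#' p <- model_params()
#' effective_fatality_hazard(p, 10, "not_prescribed")  # 3.25e-5
#' effective_fatality_hazard(p, 10, "prescribed")      # 1.29025e-5
effective_fatality_hazard <- function(params, age, strategy) {
  strategy <- match_strategy(strategy)
  mult <- if (strategy == "not_prescribed") params$rr_no_epi
          else params$p_carry + (1 - params$p_carry) * params$rr_no_epi
  base_fatality_rate(params, age) * mult
}

#' Annual twin packs purchased at a given age
#'
#' Two twin packs below \code{adult_age_packs}, one at or above it.
#'
#' @inheritParams effective_fatality_hazard
#' @return Pack count (vectorized over \code{age}).
#' @export
packs_per_year <- function(params, age) {
  ifelse(age < params$adult_age_packs,
         params$twin_packs_child, params$twin_packs_adult)
}

#' Expected cost accrued per cycle by state
#'
#' Only the allergic state accrues cost: the annual device purchase
#' (prescribed arm only) plus the expected emergency pathway
#' \eqn{p_{ED} (c_{ED} + p_{hosp} c_{hosp})}. Tolerant and dead states
#' accrue nothing. The separate food-allergy-death pathway cost is handled
#' by the engines, not here.
#'
#' @inheritParams effective_fatality_hazard
#' @param state one of [HEALTH_STATES].
#' @return Expected USD per cycle.
#' @export
cycle_cost <- function(params, age, strategy, state) {
  strategy <- match_strategy(strategy)
  state <- match.arg(state, HEALTH_STATES)
  if (state != "allergic") return(0)
  drug <- if (strategy == "prescribed")
    packs_per_year(params, age) * params$price_twin_pack else 0
  emergency <- params$p_ed_visit *
    (params$cost_ed + params$p_hospitalization * params$cost_hospitalization)
  drug + emergency
}

#' QALY weight per cycle by state
#'
#' @inheritParams cycle_cost
#' @return 1 minus the utility decrement while allergic, 1 when tolerant,
#'   0 when dead.
#' @export
cycle_utility <- function(params, state) {
  state <- match.arg(state, HEALTH_STATES)
  switch(state,
         allergic = 1 - params$utility_decrement,
         tolerant = 1,
         0)
}

#' Assemble one cycle of the transition model
#'
#' Combines the life-table background mortality, the effective food-allergy
#' fatality hazard, the one-time resolution transition and the cycle's cost
#' and utility symbols into a single cycle plan. Competing exits from the
#' allergic state are combined additively; the resolution probability at
#' \code{resolution_age} applies to the remainder after death exits,
#' \eqn{p_{res}(1 - p_{fat} - q_x)}.
#'
#' @inheritParams effective_fatality_hazard
#' @param table a \code{life_table}.
#' @return A \code{cycle_plan}: transition probability vectors
#'   \code{from_allergic} (stay / to_tolerant / to_dead_background /
#'   to_dead_food_allergy) and \code{from_tolerant}, the discount factor for
#'   the cycle, state costs and utilities, and the per-death event cost.
#' @export
build_cycle_plan <- function(params, table, age, strategy) {
  strategy <- match_strategy(strategy)
  qb <- annual_mortality(table, age)
  pf <- effective_fatality_hazard(params, age, strategy)
  ptol <- if (age == params$resolution_age)
    params$p_resolution * (1 - pf - qb) else 0
  stay <- 1 - pf - qb - ptol
  if (stay < 0)
    stop("transition remainder < 0 at age ", age,
         " (pathologically large hazards)", call. = FALSE)
  plan <- list(
    age = age,
    strategy = strategy,
    discount_factor = (1 + params$discount_rate)^(-(age - params$start_age)),
    from_allergic = c(stay = stay, to_tolerant = ptol,
                      to_dead_background = qb, to_dead_food_allergy = pf),
    from_tolerant = c(stay = 1 - qb, to_dead_background = qb),
    cost = c(allergic = cycle_cost(params, age, strategy, "allergic"),
             tolerant = 0, dead_background = 0, dead_food_allergy = 0),
    fatality_event_cost = params$cost_ed +
      params$p_hospitalization * params$cost_hospitalization,
    utility = c(allergic = cycle_utility(params, "allergic"),
                tolerant = 1, dead_background = 0, dead_food_allergy = 0)
  )
  class(plan) <- "cycle_plan"
  plan
}

arm_result <- function(strategy, mode, mean_cost, mean_qaly, p_fatality,
                       ci_cost = NULL, ci_qaly = NULL, ci_fatality = NULL,
                       n_patients = NA_integer_, seed = NA_integer_,
                       trace = NULL) {
  structure(list(strategy = strategy, mode = mode,
                 mean_cost = mean_cost, mean_qaly = mean_qaly,
                 p_fatality = p_fatality,
                 ci_cost = ci_cost, ci_qaly = ci_qaly,
                 ci_fatality = ci_fatality,
                 n_patients = n_patients, seed = seed, trace = trace),
            class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("<arm_result> %s (%s)\n", x$strategy, x$mode))
  fmt_ci <- function(ci, d) if (is.null(ci)) "" else
    sprintf("  (95%% CI %s-%s)", formatC(ci[1], format = "f", digits = d),
            formatC(ci[2], format = "f", digits = d))
  cat(sprintf("  mean cost   $%s%s\n",
              formatC(x$mean_cost, format = "f", digits = 0, big.mark = " "),
              fmt_ci(x$ci_cost, 0)))
  cat(sprintf("  mean QALYs  %.4f%s\n", x$mean_qaly, fmt_ci(x$ci_qaly, 4)))
  cat(sprintf("  fatality    %.5f%s\n", x$p_fatality,
              fmt_ci(x$ci_fatality, 6)))
  invisible(x)
}

check_engine_inputs <- function(params, table) {
  validate_params(params)
  stopifnot(inherits(table, "life_table"))
  if (params$cycle_length != 1)
    stop("the engine supports annual cycles only (cycle_length = 1)",
         call. = FALSE)
}

#' Deterministic cohort-expectation solver
#'
#' Propagates the state-occupancy vector through the cycle plans for
#' \code{horizon} annual cycles, accruing discounted costs and half-cycle
#' corrected QALYs, and returns the arm's expected outcomes. This is the
#' noise-free expectation of [run_microsim()].
#'
#' @inheritParams build_cycle_plan
#' @param keep_trace if \code{TRUE}, attach the occupancy matrix
#'   (\code{horizon + 1} rows, one per cycle boundary) to the result.
#' @return An \code{arm_result} with \code{mean_cost} (discounted USD),
#'   \code{mean_qaly} (discounted), and \code{p_fatality} (terminal
#'   occupancy of the food-allergy death state). Intervals are \code{NULL}
#'   in cohort mode.
#' @export
run_cohort <- function(params, table, strategy, keep_trace = FALSE) {
  strategy <- match_strategy(strategy)
  check_engine_inputs(params, table)
  H <- params$horizon
  occ <- c(allergic = 1, tolerant = 0, dead_background = 0,
           dead_food_allergy = 0)
  trace <- if (keep_trace)
    matrix(NA_real_, H + 1, 4, dimnames = list(NULL, names(occ)))
  if (keep_trace) trace[1, ] <- occ
  cost <- 0
  qaly <- 0
  for (t in seq_len(H) - 1L) {
    plan <- build_cycle_plan(params, table, params$start_age + t, strategy)
    pA <- plan$from_allergic
    pT <- plan$from_tolerant
    new_occ <- c(
      allergic = occ[["allergic"]] * pA[["stay"]],
      tolerant = occ[["tolerant"]] * pT[["stay"]] +
        occ[["allergic"]] * pA[["to_tolerant"]],
      dead_background = occ[["dead_background"]] +
        occ[["allergic"]] * pA[["to_dead_background"]] +
        occ[["tolerant"]] * pT[["to_dead_background"]],
      dead_food_allergy = occ[["dead_food_allergy"]] +
        occ[["allergic"]] * pA[["to_dead_food_allergy"]]
    )
    d <- plan$discount_factor
    cost <- cost + d * occ[["allergic"]] *
      (plan$cost[["allergic"]] +
         pA[["to_dead_food_allergy"]] * plan$fatality_event_cost)
    qaly <- qaly + d * 0.5 * (sum(plan$utility * occ) +
                              sum(plan$utility * new_occ))
    occ <- new_occ
    if (keep_trace) trace[t + 2L, ] <- occ
  }
  arm_result(strategy, "cohort", cost, qaly, occ[["dead_food_allergy"]],
             trace = trace)
}

#' Patient-level microsimulation
#'
#' First-order Monte-Carlo realization of the same model: each patient's
#' trajectory is simulated by categorical draws from the cycle plans, with
#' device carriage drawn as an independent Bernoulli per anaphylaxis-risk
#' cycle in the prescribed arm, and ED visits / admissions drawn per cycle.
#' Accounting (discounting, half-cycle utility weighting, death-cycle
#' emergency cost) is identical to [run_cohort()], so the microsimulation
#' means converge to the cohort expectations.
#'
#' Draws are generated cycle by cycle across the patient vector from one
#' seeded stream in a fixed order, so results are bit-reproducible given
#' \code{(seed, n_patients)}.
#'
#' @inheritParams build_cycle_plan
#' @param n_patients number of simulated patients (>= 1).
#' @param seed integer seed for the run; the caller's RNG state is restored
#'   on exit.
#' @return An \code{arm_result} with normal-approximation 95% intervals for
#'   mean cost, mean QALYs and the lifetime food-allergy fatality
#'   probability.
#' @export
run_microsim <- function(params, table, strategy, n_patients = 1e5,
                         seed = 1L) {
  strategy <- match_strategy(strategy)
  check_engine_inputs(params, table)
  stopifnot(n_patients >= 1)
  n <- as.integer(n_patients)

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)

  H <- params$horizon
  prescribed <- strategy == "prescribed"
  rr <- params$rr_no_epi
  pc <- params$p_carry
  p_ed <- params$p_ed_visit
  ph <- params$p_hospitalization
  ced <- params$cost_ed
  chosp <- params$cost_hospitalization
  fat_cost <- ced + ph * chosp
  u_all <- 1 - params$utility_decrement

  state <- rep.int(1L, n)  # 1 allergic, 2 tolerant, 3 dead_bg, 4 dead_fa
  cost <- numeric(n)
  qaly <- numeric(n)

  for (t in seq_len(H) - 1L) {
    age <- params$start_age + t
    disc <- (1 + params$discount_rate)^(-t)
    qb <- annual_mortality(table, age)
    base <- base_fatality_rate(params, age)
    at_res_age <- age == params$resolution_age

    # index both at-risk sets by state at cycle START: a patient resolving
    # this cycle must not also take this cycle's tolerant-state draw
    iA <- which(state == 1L)
    iT <- which(state == 2L)
    nA <- length(iA)
    if (nA) {
      pf <- if (prescribed) {
        carry <- stats::runif(nA) < pc
        base * ifelse(carry, 1, rr)
      } else rep.int(base * rr, nA)
      u_tr <- stats::runif(nA)
      to_df <- u_tr < pf
      to_db <- !to_df & u_tr < pf + qb
      p_tol <- if (at_res_age) params$p_resolution * (1 - pf - qb) else 0
      to_tol <- if (at_res_age)
        !to_df & !to_db & u_tr < pf + qb + p_tol else rep.int(FALSE, nA)

      u_ed <- stats::runif(nA)
      u_h <- stats::runif(nA)
      ed <- u_ed < p_ed
      drug <- if (prescribed)
        packs_per_year(params, age) * params$price_twin_pack else 0
      cost[iA] <- cost[iA] + disc *
        (drug + ed * (ced + (u_h < ph) * chosp) + to_df * fat_cost)

      u_end <- rep.int(u_all, nA)
      u_end[to_tol] <- 1
      u_end[to_df | to_db] <- 0
      qaly[iA] <- qaly[iA] + disc * 0.5 * (u_all + u_end)

      new_state <- rep.int(1L, nA)
      new_state[to_tol] <- 2L
      new_state[to_db] <- 3L
      new_state[to_df] <- 4L
      state[iA] <- new_state
    }

    if (length(iT)) {
      die <- stats::runif(length(iT)) < qb
      qaly[iT] <- qaly[iT] + disc * 0.5 * (1 + !die)
      state[iT[die]] <- 3L
    }
  }

  ci <- function(m, s) m + c(-1, 1) * stats::qnorm(0.975) * s
  mc <- mean(cost)
  mq <- mean(qaly)
  pfat <- mean(state == 4L)
  arm_result(strategy, "microsim", mc, mq, pfat,
             ci_cost = ci(mc, stats::sd(cost) / sqrt(n)),
             ci_qaly = ci(mq, stats::sd(qaly) / sqrt(n)),
             ci_fatality = ci(pfat, sqrt(pfat * (1 - pfat) / n)),
             n_patients = n, seed = as.integer(seed))
}
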