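# Value-based pricing: ICER as a function of the twin-pack price, the
# ceiling-price bisection, and the named scenario suite.

# Cohort-mode comparison with per-arm parameter sets (arm-specific
# overrides, e.g. doubled hospitalization in the no-prescription arm, enter
# here).
ce_for_arm_params <- function(params_prescribed, params_not_prescribed,
                              table, wtp) {
  compare_arms(run_cohort(params_prescribed, table, "prescribed"),
               run_cohort(params_not_prescribed, table, "not_prescribed"),
               wtp = wtp)
}

with_price <- function(params, price) {
  params$price_twin_pack <- price
  params
}

#' ICER at a given twin-pack price
#'
#' Clones the parameter set with \code{price_twin_pack = price}, evaluates
#' both arms in cohort-expectation mode, and returns the comparison.
#' Because only the prescribed arm buys devices, incremental QALYs are
#' price-invariant and the ICER is continuous and strictly increasing in
#' price.
#'
#' @param params \code{model_params}.
#' @param table a \code{life_table}.
#' @param price twin-pack price in USD per year (>= 0).
#' @param wtp willingness-to-pay threshold, USD/QALY.
#' @param scenario optional \code{scenario_spec} applied (including
#'   arm-specific overrides) before evaluation.
#' @return A \code{ce_result}.
#' @export
icer_at_price <- function(params, table, price, wtp = 1e5, scenario = NULL) {
  stopifnot(price >= 0)
  pp <- params
  pn <- params
  if (!is.null(scenario)) {
    pp <- apply_scenario(params, scenario, "prescribed")
    pn <- apply_scenario(params, scenario, "not_prescribed")
  }
  ce_for_arm_params(with_price(pp, price), with_price(pn, price), table, wtp)
}

#' Solve the value-based ceiling price
#'
#' Bisection on the twin-pack price for the largest price at which the
#' prescription strategy's ICER does not exceed the willingness-to-pay
#' threshold, i.e. the root of \eqn{NMB(price) = 0} (NMB is linear and
#' strictly decreasing in price, so the root is unique). The bracket must
#' straddle the threshold: ICER (equivalently NMB) below \code{wtp} at the
#' low end and above it at the high end.
#'
#' @inheritParams icer_at_price
#' @param bracket length-2 price interval to search.
#' @param tol internal price tolerance in USD for the bisection root. The
#'   default (1e-6) locates the root far more precisely than the cent
#'   precision at which \code{ceiling_price} is reported, so that
#'   \code{icer_at_ceiling} matches \code{wtp} to within a relative 1e-4.
#' @param max_iter iteration cap.
#' @return A \code{price_solve_result}: \code{ceiling_price} (USD, cent
#'   precision), \code{icer_at_ceiling} (the ICER at the unrounded root),
#'   \code{wtp}, the bracket and tolerance used, scenario name and engine
#'   mode.
#' @export
solve_price_ceiling <- function(params, table, wtp = 1e5,
                                bracket = c(0, 5000), tol = 1e-6,
                                max_iter = 60, scenario = NULL) {
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2], bracket[1] >= 0)
  f <- function(price) icer_at_price(params, table, price, wtp, scenario)
  lo <- bracket[1]
  hi <- bracket[2]
  ce_lo <- f(lo)
  ce_hi <- f(hi)
  if (!is.finite(ce_lo$nmb) || !is.finite(ce_hi$nmb))
    stop("non-finite net benefit inside bracket (degenerate comparison: ",
         "delta QALY = ", format(ce_lo$delta_qaly), ")", call. = FALSE)
  # NMB decreasing in price: cost-effective at lo, not at hi.
  if (ce_lo$nmb <= 0)
    stop("bracket does not straddle the threshold: ICER at price ",
         lo, " already exceeds wtp = ", wtp, call. = FALSE)
  if (ce_hi$nmb >= 0)
    stop("bracket does not straddle the threshold: ICER at price ",
         hi, " is still below wtp = ", wtp, call. = FALSE)
  iter <- 0
  while (hi - lo > tol && iter < max_iter) {
    mid <- (lo + hi) / 2
    if (f(mid)$nmb >= 0) lo <- mid else hi <- mid
    iter <- iter + 1
  }
  root <- (lo + hi) / 2
  structure(list(
    scenario_name = if (is.null(scenario)) "base_case" else scenario$name,
    wtp = wtp,
    ceiling_price = round(root, 2),
    icer_at_ceiling = f(root)$icer,
    bracket = bracket, tol = tol, iterations = iter,
    engine_mode = "cohort"),
    class = "price_solve_result")
}

#' @export
print.price_solve_result <- function(x, ...) {
  cat(sprintf(
    "<price_solve_result> %s: ceiling $%.2f per twin pack (ICER $%s at wtp $%s)\n",
    x$scenario_name, x$ceiling_price,
    formatC(x$icer_at_ceiling, format = "f", digits = 0, big.mark = " "),
    formatC(x$wtp, format = "d", big.mark = " ")))
  invisible(x)
}

#' Run the named scenario suite
#'
#' For each scenario: the value-based ceiling price at \code{wtp} and the
#' cost-effectiveness of the reference price (default $715). Arm-specific
#' overrides are applied only to their designated arm.
#'
#' @inheritParams icer_at_price
#' @param scenarios named list of \code{scenario_spec} (default
#'   [builtin_scenarios()]).
#' @param price_ref reference twin-pack price evaluated per scenario.
#' @param bracket,tol passed to [solve_price_ceiling()].
#' @return A data frame with one row per scenario: ceiling price, ICER at
#'   the ceiling, ICER and classification at \code{price_ref}.
#' @export
run_scenario_suite <- function(params, table, scenarios = builtin_scenarios(),
                               wtp = 1e5, price_ref = 715,
                               bracket = c(0, 5000), tol = 1e-6) {
  rows <- lapply(scenarios, function(sc) {
    sol <- solve_price_ceiling(params, table, wtp, bracket, tol,
                               scenario = sc)
    ce <- icer_at_price(params, table, price_ref, wtp, scenario = sc)
    data.frame(scenario = sc$name,
               wtp = wtp,
               ceiling_price = sol$ceiling_price,
               icer_at_ceiling = sol$icer_at_ceiling,
               price_ref = price_ref,
               icer_at_ref = ce$icer,
               classification_at_ref = ce$classification,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("scenario_suite", class(out))
  out
}

#' Price sweep of the ICER
#'
#' Evaluates the cohort-mode ICER over a grid of twin-pack prices, the
#' deterministic analogue of a price sensitivity sweep.
#'
#' @inheritParams icer_at_price
#' @param prices numeric vector of twin-pack prices.
#' @return Data frame with columns \code{price}, \code{delta_cost},
#'   \code{delta_qaly}, \code{icer}, \code{nmb}, \code{classification}.
#' @export
sweep_price <- function(params, table, prices = seq(0, 715, by = 5),
                        wtp = 1e5, scenario = NULL) {
  rows <- lapply(prices, function(p) {
    ce <- icer_at_price(params, table, p, wtp, scenario)
    data.frame(price = p, delta_cost = ce$delta_cost,
               delta_qaly = ce$delta_qaly, icer = ce$icer, nmb = ce$nmb,
               classification = ce$classification,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
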