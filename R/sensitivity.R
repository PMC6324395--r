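# One-way deterministic sensitivity analysis (tornado) and probabilistic
# sensitivity analysis (PSA) with cost-effectiveness acceptability curves.

#' Default one-way sensitivity ranges
#'
#' The published low/high range for every varied model input: fatality rates
#' to ten-fold their base values, reaction and ED-visit rates, carriage,
#' hospitalization, resolution probability and age, the price and cost 95%
#' CIs, the risk multiplier (10 to 100), start age, discount rate and the
#' utility decrement.
#'
#' @return Named list of \code{c(low, high)} pairs.
#' @export
default_sensitivity_ranges <- function() {
  list(
    fatality_rate_child = c(3.25e-6, 33.0e-6),
    fatality_rate_adult = c(1.81e-6, 18.1e-6),
    p_reaction = c(0.05, 0.45),
    p_ed_visit = c(0.005, 0.035),
    p_carry = c(0.40, 1.00),
    p_hospitalization = c(0.05, 0.45),
    p_resolution = c(0.15, 0.30),
    resolution_age = c(4, 22),
    price_twin_pack = c(685, 743),
    cost_hospitalization = c(5732, 6066),
    cost_ed = c(689, 693),
    rr_no_epi = c(10, 100),
    start_age = c(0, 5),
    discount_rate = c(0, 0.03),
    utility_decrement = c(0.02, 0.11)
  )
}

#' One-way deterministic sensitivity analysis
#'
#' Varies one parameter at a time to its range endpoints (all others at
#' their base values), evaluates the cohort-mode comparison at each end,
#' and returns the entries in tornado order (largest ICER spread first).
#'
#' @param params base \code{model_params}.
#' @param table a \code{life_table}.
#' @param ranges named list of \code{c(low, high)} pairs (default
#'   [default_sensitivity_ranges()]); every range must lie in the
#'   parameter's validity domain.
#' @param wtp willingness-to-pay threshold, USD/QALY.
#' @return Data frame with one row per parameter: \code{param},
#'   \code{low_value}, \code{high_value}, \code{icer_at_low},
#'   \code{icer_at_high}, \code{spread}, and \code{crosses_wtp} (whether
#'   cost-effectiveness at \code{wtp} flips across the range).
#' @export
one_way_dsa <- function(params, table, ranges = default_sensitivity_ranges(),
                        wtp = 1e5) {
  stopifnot(length(ranges) > 0, !is.null(names(ranges)))
  eval_at <- function(field, value) {
    p <- params
    p[[field]] <- value
    validate_params(p)
    ce_for_arm_params(p, p, table, wtp)
  }
  rows <- lapply(names(ranges), function(field) {
    rg <- ranges[[field]]
    if (length(rg) != 2 || rg[1] > rg[2])
      stop("range for ", field, " must be c(low, high) with low <= high",
           call. = FALSE)
    ce_lo <- eval_at(field, rg[1])
    ce_hi <- eval_at(field, rg[2])
    data.frame(param = field, low_value = rg[1], high_value = rg[2],
               icer_at_low = ce_lo$icer, icer_at_high = ce_hi$icer,
               spread = abs(ce_hi$icer - ce_lo$icer),
               crosses_wtp = (ce_lo$nmb > 0) != (ce_hi$nmb > 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(-out$spread), , drop = FALSE]
}

#' Parameter uncertainty distribution
#'
#' Describes the sampling distribution of one model input for probabilistic
#' sensitivity analysis. Supported families: \code{uniform(min, max)};
#' \code{gamma} moment-matched to a mean and normal-approximation 95% CI
#' (\code{sd = (hi - lo) / 3.92}); \code{lognormal} matched to a 95% CI on
#' the log scale; \code{beta} moment-matched to a mean and sd; and
#' \code{point} (degenerate).
#'
#' @param param_name name of the \code{model_params} field.
#' @param kind one of \code{"uniform"}, \code{"gamma"}, \code{"lognormal"},
#'   \code{"beta"}, \code{"point"}.
#' @param ... family parameters: \code{min,max} (uniform); \code{mean,lo,hi}
#'   (gamma); \code{lo,hi} (lognormal); \code{mean,sd} (beta);
#'   \code{value} (point).
#' @return A \code{param_distribution} with a \code{sample(n)} function.
#' @export
param_distribution <- function(param_name,
                               kind = c("uniform", "gamma", "lognormal",
                                        "beta", "point"),
                               ...) {
  kind <- match.arg(kind)
  args <- list(...)
  z95 <- 2 * stats::qnorm(0.975)
  sampler <- switch(kind,
    uniform = {
      stopifnot(args$min <= args$max)
      function(n) stats::runif(n, args$min, args$max)
    },
    gamma = {
      sd <- (args$hi - args$lo) / z95
      vr <- sd^2
      shape <- args$mean^2 / vr
      rate <- args$mean / vr
      function(n) stats::rgamma(n, shape = shape, rate = rate)
    },
    lognormal = {
      meanlog <- (log(args$lo) + log(args$hi)) / 2
      sdlog <- (log(args$hi) - log(args$lo)) / z95
      function(n) stats::rlnorm(n, meanlog, sdlog)
    },
    beta = {
      m <- args$mean
      vr <- args$sd^2
      stopifnot(vr < m * (1 - m))
      nu <- m * (1 - m) / vr - 1
      function(n) stats::rbeta(n, m * nu, (1 - m) * nu)
    },
    point = function(n) rep.int(args$value, n)
  )
  structure(list(param_name = param_name, kind = kind, args = args,
                 sample = sampler),
            class = "param_distribution")
}

#' Default PSA distributions
#'
#' The packaged uncertainty model: lognormal fatality rates matched to
#' their published 95% CIs; gamma costs (device price, hospitalization, ED
#' visit) matched to theirs; and uniform distributions over the published
#' sensitivity ranges for the probabilities and the utility decrement,
#' which have no printed CIs. Parameters are sampled independently.
#'
#' @return Named list of \code{param_distribution} objects.
#' @export
default_param_distributions <- function() {
  d <- list(
    param_distribution("fatality_rate_child", "lognormal",
                       lo = 1.73e-6, hi = 6.10e-6),
    param_distribution("fatality_rate_adult", "lognormal",
                       lo = 0.94e-6, hi = 3.45e-6),
    param_distribution("price_twin_pack", "gamma",
                       mean = 715, lo = 685, hi = 743),
    param_distribution("cost_hospitalization", "gamma",
                       mean = 5899, lo = 5732, hi = 6066),
    param_distribution("cost_ed", "gamma", mean = 691, lo = 689, hi = 693),
    param_distribution("p_reaction", "uniform", min = 0.05, max = 0.45),
    param_distribution("p_ed_visit", "uniform", min = 0.005, max = 0.035),
    param_distribution("p_carry", "uniform", min = 0.40, max = 1.00),
    param_distribution("p_hospitalization", "uniform",
                       min = 0.05, max = 0.45),
    param_distribution("p_resolution", "uniform", min = 0.15, max = 0.30),
    param_distribution("utility_decrement", "uniform",
                       min = 0.02, max = 0.11)
  )
  stats::setNames(d, vapply(d, `[[`, "", "param_name"))
}

sample_param_set <- function(params, distributions, resample_cap = 100) {
  for (attempt in seq_len(resample_cap)) {
    p <- params
    for (d in distributions) p[[d$param_name]] <- d$sample(1)
    ok <- tryCatch({ validate_params(p); TRUE },
                   epivalue_validation_error = function(e) FALSE)
    if (ok) return(p)
  }
  stop("could not draw a valid parameter set in ", resample_cap,
       " attempts", call. = FALSE)
}

#' Probabilistic sensitivity analysis
#'
#' Samples \code{n_trials} joint parameter draws from the uncertainty
#' distributions, evaluates both strategy arms per draw (cohort-expectation
#' mode by default, so only parameter uncertainty enters), and summarizes
#' the fraction of draws cost-effective at \code{wtp} together with the
#' cost-effectiveness acceptability curve (CEAC) over \code{wtp_grid}.
#'
#' @inheritParams one_way_dsa
#' @param distributions named list of \code{param_distribution} (default
#'   [default_param_distributions()]).
#' @param n_trials number of joint draws (>= 1).
#' @param wtp_grid thresholds at which the CEAC is evaluated.
#' @param seed integer seed; draws (and microsimulation streams, if used)
#'   are reproducible given it.
#' @param engine \code{"cohort"} (default) or \code{"microsim"} per trial.
#' @param n_patients microsimulation size per arm per trial (microsim
#'   engine only).
#' @param resample_cap attempts allowed to redraw an invalid joint sample
#'   before erroring.
#' @return A \code{psa_result}: per-trial deltas, the fraction
#'   cost-effective at \code{wtp}, and the CEAC data frame.
#' @export
run_psa <- function(params, table,
                    distributions = default_param_distributions(),
                    n_trials = 1000, wtp = 1e5,
                    wtp_grid = seq(5e4, 2e5, by = 1e4),
                    seed = 1L, engine = c("cohort", "microsim"),
                    n_patients = 1e4, resample_cap = 100) {
  engine <- match.arg(engine)
  stopifnot(n_trials >= 1)
  check_engine_inputs(params, table)

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  msim_seeds <- if (engine == "microsim")
    matrix(sample.int(2^31 - 2, 2 * n_trials), ncol = 2)

  dc <- numeric(n_trials)
  dq <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    p_i <- sample_param_set(params, distributions, resample_cap)
    if (engine == "cohort") {
      a1 <- run_cohort(p_i, table, "prescribed")
      a0 <- run_cohort(p_i, table, "not_prescribed")
    } else {
      a1 <- run_microsim(p_i, table, "prescribed", n_patients,
                         seed = msim_seeds[i, 1])
      a0 <- run_microsim(p_i, table, "not_prescribed", n_patients,
                         seed = msim_seeds[i, 2])
    }
    dc[i] <- a1$mean_cost - a0$mean_cost
    dq[i] <- a1$mean_qaly - a0$mean_qaly
  }
  ceac <- data.frame(
    wtp = wtp_grid,
    p_cost_effective = vapply(wtp_grid,
                              function(w) mean(w * dq - dc > 0), 0))
  structure(list(
    n_trials = n_trials, seed = as.integer(seed), engine = engine,
    wtp = wtp,
    draws = data.frame(trial = seq_len(n_trials), delta_cost = dc,
                       delta_qaly = dq),
    fraction_cost_effective = mean(wtp * dq - dc > 0),
    ceac = ceac),
    class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf(
    "<psa_result> %d trials (%s engine, seed %d)\n", x$n_trials, x$engine,
    x$seed))
  cat(sprintf("  cost-effective at $%s/QALY: %.1f%% of trials\n",
              formatC(x$wtp, format = "d", big.mark = " "),
              100 * x$fraction_cost_effective))
  invisible(x)
}
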