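# Model parameters and named scenarios.

#' Base-case model parameters
#'
#' Constructs the full input vector of the decision model: annual food-allergy
#' fatality rates, reaction and emergency-department (ED) probabilities,
#' device carriage, costs (2018 USD), discounting, the utility decrement while
#' allergic, and the structural constants (pack counts, age boundaries,
#' horizon). Defaults are the published base case; any field can be
#' overridden by name.
#'
#' @param ... named overrides of individual fields (see Details).
#'
#' @details Fields and base values:
#' \describe{
#'   \item{fatality_rate_child}{annual food-allergy fatality probability,
#'     ages below \code{adult_age_fatality} (3.25e-6, i.e. 3.25 per million
#'     person-years).}
#'   \item{fatality_rate_adult}{annual fatality probability at
#'     \code{adult_age_fatality} and above (1.81e-6).}
#'   \item{rr_no_epi}{risk multiplier on the fatality rate when no device is
#'     available at the time of anaphylaxis (10).}
#'   \item{p_reaction}{annual probability of accidental peanut exposure with
#'     symptoms (0.07). Carries no cost/utility consequence in the base
#'     model; retained as a sensitivity axis.}
#'   \item{p_ed_visit}{annual probability of a reaction prompting ED
#'     evaluation (0.01).}
#'   \item{p_carry}{probability a prescribed person has a device available
#'     and administered at anaphylaxis (0.67).}
#'   \item{p_hospitalization}{probability of admission after an ED
#'     anaphylaxis visit (0.35).}
#'   \item{p_resolution}{probability of spontaneous peanut tolerance,
#'     applied once at \code{resolution_age} (0.22 at age 4).}
#'   \item{price_twin_pack}{USD per twin pack per year (715).}
#'   \item{cost_hospitalization, cost_ed}{USD per event (5899, 691).}
#'   \item{twin_packs_child, twin_packs_adult}{annual twin packs purchased
#'     while allergic and prescribed (2 below \code{adult_age_packs}, 1 at or
#'     above it).}
#'   \item{adult_age_packs}{age at which the supply drops to one pack (19).}
#'   \item{adult_age_fatality}{age at which the adult fatality rate applies
#'     (20).}
#'   \item{start_age, horizon, cycle_length}{cohort entry age (0), number of
#'     annual cycles (80), cycle length in years (1).}
#'   \item{discount_rate}{annual discount rate applied to both costs and
#'     QALYs (0.03).}
#'   \item{utility_decrement}{QALY weight reduction while allergic (0.09).}
#' }
#'
#' @return A validated object of class \code{model_params}.
#' @seealso [validate_params()], [builtin_scenarios()], [load_config()]
#' @export
#' @examples
#' p <- model_params()
#' p$price_twin_pack
#' model_params(rr_no_epi = 100)$rr_no_epi
model_params <- function(...) {
  p <- list(
    fatality_rate_child = 3.25e-6,
    fatality_rate_adult = 1.81e-6,
    rr_no_epi = 10,
    p_reaction = 0.07,
    p_ed_visit = 0.01,
    p_carry = 0.67,
    p_hospitalization = 0.35,
    p_resolution = 0.22,
    resolution_age = 4,
    price_twin_pack = 715,
    cost_hospitalization = 5899,
    cost_ed = 691,
    twin_packs_child = 2,
    twin_packs_adult = 1,
    adult_age_packs = 19,
    adult_age_fatality = 20,
    start_age = 0,
    horizon = 80,
    cycle_length = 1,
    discount_rate = 0.03,
    utility_decrement = 0.09
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all overrides must be named", call. = FALSE)
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    p[names(dots)] <- dots
  }
  class(p) <- "model_params"
  validate_params(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  for (nm in names(unclass(x)))
    cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

param_field_names <- function() names(unclass(model_params()))

#' Validate a parameter set
#'
#' Checks every invariant of the model input vector: probabilities and annual
#' rates in \[0, 1\], non-negative costs, a risk multiplier of at least 1,
#' non-negative integer pack counts, and coherent age/horizon structure.
#'
#' @param params a \code{model_params} object (or bare named list with the
#'   same fields).
#' @return \code{params}, invisibly unchanged, if valid; otherwise an error of
#'   class \code{epivalue_validation_error} whose message lists every violated
#'   constraint as \code{field (value): constraint}.
#' @export
validate_params <- function(params) {
  v <- character(0)
  chk <- function(ok, field, constraint) {
    if (!isTRUE(ok))
      v <<- c(v, sprintf("%s (%s): %s", field,
                         paste(format(params[[field]]), collapse = ","),
                         constraint))
  }
  num1 <- function(f) is.numeric(params[[f]]) && length(params[[f]]) == 1 &&
    is.finite(params[[f]])
  for (f in c("fatality_rate_child", "fatality_rate_adult", "p_reaction",
              "p_ed_visit", "p_carry", "p_hospitalization", "p_resolution",
              "discount_rate", "utility_decrement"))
    chk(num1(f) && params[[f]] >= 0 && params[[f]] <= 1, f,
        "probability/rate out of [0,1]")
  for (f in c("price_twin_pack", "cost_hospitalization", "cost_ed"))
    chk(num1(f) && params[[f]] >= 0, f, "cost must be >= 0")
  chk(num1("rr_no_epi") && params$rr_no_epi >= 1, "rr_no_epi",
      "risk multiplier must be >= 1")
  for (f in c("twin_packs_child", "twin_packs_adult"))
    chk(num1(f) && params[[f]] >= 0 && params[[f]] == round(params[[f]]), f,
        "twin pack count must be a non-negative integer")
  for (f in c("resolution_age", "adult_age_packs", "adult_age_fatality",
              "start_age"))
    chk(num1(f) && params[[f]] >= 0 && params[[f]] == round(params[[f]]), f,
        "age must be a non-negative integer")
  chk(num1("horizon") && params$horizon >= 1 &&
        params$horizon == round(params$horizon), "horizon",
      "horizon must be a positive integer number of cycles")
  chk(num1("cycle_length") && params$cycle_length > 0, "cycle_length",
      "cycle length must be > 0")
  if (length(v))
    stop(structure(
      class = c("epivalue_validation_error", "error", "condition"),
      list(message = paste0("invalid model parameters:\n  ",
                            paste(v, collapse = "\n  ")),
           call = sys.call(-1), violations = v)))
  invisible(params)
}

#' Define a named scenario
#'
#' A scenario is a named set of parameter overrides, optionally with
#' arm-specific overrides (applied to just one strategy, e.g. doubling the
#' hospitalization probability only in the arm without a personal device).
#'
#' @param name scenario label.
#' @param overrides named list of parameter overrides applied to both arms.
#' @param arm_overrides named list with optional elements \code{prescribed}
#'   and \code{not_prescribed}, each a named list of overrides applied to
#'   that arm only (after the common overrides).
#' @return An object of class \code{scenario_spec}.
#' @export
scenario_spec <- function(name, overrides = list(), arm_overrides = list()) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  fields <- names(unclass(model_params()))
  bad <- setdiff(names(overrides), fields)
  if (length(bad))
    stop("scenario '", name, "' overrides unknown parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad_arm <- setdiff(names(arm_overrides), c("prescribed", "not_prescribed"))
  if (length(bad_arm))
    stop("arm_overrides names must be 'prescribed'/'not_prescribed'",
         call. = FALSE)
  for (arm in names(arm_overrides)) {
    bad <- setdiff(names(arm_overrides[[arm]]), fields)
    if (length(bad))
      stop("scenario '", name, "' arm '", arm,
           "' overrides unknown parameter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, overrides = overrides,
                 arm_overrides = arm_overrides),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  fmt <- function(o) if (length(o))
    paste(names(o), vapply(o, format, ""), sep = "=", collapse = ", ")
  else "(none)"
  cat("<scenario_spec> ", x$name, "\n  overrides: ", fmt(x$overrides), "\n",
      sep = "")
  for (arm in names(x$arm_overrides))
    cat("  ", arm, ": ", fmt(x$arm_overrides[[arm]]), "\n", sep = "")
  invisible(x)
}

#' Apply a scenario to a parameter set
#'
#' Applies the scenario's common overrides and, if \code{strategy} is given,
#' that arm's specific overrides. Application is idempotent and
#' order-independent for disjoint override sets; the result is re-validated.
#'
#' @param params base \code{model_params}.
#' @param scenario a \code{scenario_spec}.
#' @param strategy \code{NULL}, \code{"prescribed"} or
#'   \code{"not_prescribed"}.
#' @return A validated \code{model_params}.
#' @export
apply_scenario <- function(params, scenario, strategy = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"))
  p <- unclass(params)
  p[names(scenario$overrides)] <- scenario$overrides
  if (!is.null(strategy)) {
    strategy <- match.arg(strategy, c("prescribed", "not_prescribed"))
    ov <- scenario$arm_overrides[[strategy]]
    p[names(ov)] <- ov
  }
  class(p) <- "model_params"
  validate_params(p)
  p
}

#' Built-in scenarios
#'
#' The named sensitivity scenarios of the analysis: the base case; a 100-fold
#' risk multiplier for lacking a device (\code{rr100}); perfect carriage and
#' use (\code{perfect_carriage}); their combination; doubled hospitalization
#' probability in the no-prescription arm only (\code{hosp_doubled});
#' a 10-fold inflation of both background food-allergy fatality rates
#' (\code{fatality_x10}); and the combinations
#' \code{fatality_x10_perfect_carriage} and \code{rr100_fatality_x10}.
#'
#' @return Named list of \code{scenario_spec} objects.
#' @export
builtin_scenarios <- function() {
  base <- model_params()
  x10c <- base$fatality_rate_child * 10
  x10a <- base$fatality_rate_adult * 10
  specs <- list(
    scenario_spec("base_case"),
    scenario_spec("rr100", list(rr_no_epi = 100)),
    scenario_spec("perfect_carriage", list(p_carry = 1.0)),
    scenario_spec("rr100_perfect_carriage",
                  list(rr_no_epi = 100, p_carry = 1.0)),
    scenario_spec("hosp_doubled",
                  arm_overrides = list(
                    not_prescribed = list(p_hospitalization = 0.70))),
    scenario_spec("fatality_x10",
                  list(fatality_rate_child = x10c, fatality_rate_adult = x10a)),
    scenario_spec("fatality_x10_perfect_carriage",
                  list(fatality_rate_child = x10c, fatality_rate_adult = x10a,
                       p_carry = 1.0)),
    scenario_spec("rr100_fatality_x10",
                  list(rr_no_epi = 100,
                       fatality_rate_child = x10c, fatality_rate_adult = x10a))
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}
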