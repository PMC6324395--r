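# Incremental cost-effectiveness of one arm against another.

#' Compare two strategy arms
#'
#' Computes incremental cost and QALYs of \code{intervention} over
#' \code{comparator}, the ICER, net monetary benefit (NMB) at a
#' willingness-to-pay threshold, and a classification with dominance
#' handling.
#'
#' @param intervention,comparator \code{arm_result} objects from the same
#'   model inputs, differing only in strategy (and any deliberate
#'   arm-specific overrides).
#' @param wtp willingness-to-pay threshold in USD per QALY.
#' @param qaly_tol incremental QALYs smaller than this in magnitude are
#'   treated as zero (no ICER is formed); guards against microsimulation
#'   noise.
#' @return A \code{ce_result} with fields \code{delta_cost},
#'   \code{delta_qaly}, \code{icer} (NA when undefined), \code{nmb},
#'   \code{wtp}, \code{classification} (one of \code{cost_effective},
#'   \code{not_cost_effective}, \code{dominant}, \code{dominated}) and
#'   \code{icer_undefined} (TRUE when both deltas are within tolerance of
#'   zero). NMB is \eqn{wtp \cdot \Delta QALY - \Delta cost}; the
#'   classification always agrees with the NMB sign except in the dominance
#'   cases, where it is implied.
#' @export
#' @examples
#' p <- model_params()
#' lt <- synth_life_table()
#' ce <- compare_arms(run_cohort(p, lt, "prescribed"),
#'                    run_cohort(p, lt, "not_prescribed"), wtp = 1e5)
#' ce$icer
compare_arms <- function(intervention, comparator, wtp = 1e5,
                         qaly_tol = 1e-9) {
  stopifnot(inherits(intervention, "arm_result"),
            inherits(comparator, "arm_result"))
  if (identical(intervention$strategy, comparator$strategy))
    warning("comparing an arm against the same strategy label")
  dc <- intervention$mean_cost - comparator$mean_cost
  dq <- intervention$mean_qaly - comparator$mean_qaly
  nmb <- wtp * dq - dc
  undefined <- abs(dq) < qaly_tol
  icer <- if (undefined) NA_real_ else dc / dq
  classification <-
    if (!undefined && dq > 0 && dc <= 0) "dominant"
    else if (dq <= 0 && dc > 0) "dominated"
    else if (nmb > 0) "cost_effective"
    else "not_cost_effective"
  structure(list(delta_cost = dc, delta_qaly = dq, icer = icer,
                 nmb = nmb, wtp = wtp, classification = classification,
                 icer_undefined = undefined),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result>\n")
  cat(sprintf("  delta cost  $%s\n",
              formatC(x$delta_cost, format = "f", digits = 2,
                      big.mark = " ")))
  cat(sprintf("  delta QALY  %.6f\n", x$delta_qaly))
  cat(sprintf("  ICER        %s\n",
              if (is.na(x$icer)) "undefined"
              else paste0("$", formatC(x$icer, format = "f", digits = 0,
                                       big.mark = " "), " per QALY")))
  cat(sprintf("  NMB @ $%s/QALY: $%s (%s)\n",
              formatC(x$wtp, format = "d", big.mark = " "),
              formatC(x$nmb, format = "f", digits = 2, big.mark = " "),
              x$classification))
  invisible(x)
}
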