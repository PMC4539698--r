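## ---------------------------------------------------------------------------
## Pairwise incremental cost-effectiveness analysis and net-benefit helpers.
## ---------------------------------------------------------------------------

#' Incremental cost-effectiveness analysis of two arms
#'
#' Computes incremental cost, QALYs and life years of an intervention over a
#' reference, and the ICER on unrounded accumulators. When the intervention
#' is cheaper and at least as effective (or no dearer and strictly more
#' effective) it is `DOMINATING`; the mirror case is `DOMINATED`; exact ties
#' are `EQUIVALENT`; otherwise the `icer` is the cost per QALY gained (or per
#' QALY forgone, in the south-west quadrant).
#'
#' @param reference,intervention `copd_arm_result` objects from the same
#'   settings and horizon.
#' @return A `copd_incremental`: `delta_cost`, `delta_qalys`, `delta_ly`,
#'   `icer` (NA under a dominance label), and `label` (`"ICER"`,
#'   `"DOMINATING"`, `"DOMINATED"`, or `"EQUIVALENT"`).
#' @export
incremental_analysis <- function(reference, intervention) {
  stopifnot(inherits(reference, "copd_arm_result"),
            inherits(intervention, "copd_arm_result"))
  if (!isTRUE(all.equal(reference$settings, intervention$settings, tolerance = 1e-12))) {
    stop("arm results come from different settings or horizons")
  }
  dc <- intervention$total_cost - reference$total_cost
  dq <- intervention$qalys - reference$qalys
  dl <- intervention$life_years - reference$life_years

  label <- if (dq == 0 && dc == 0) "EQUIVALENT"
    else if ((dc <= 0 && dq > 0) || (dc < 0 && dq >= 0)) "DOMINATING"
    else if ((dc >= 0 && dq < 0) || (dc > 0 && dq <= 0)) "DOMINATED"
    else "ICER"
  structure(list(
    comparison = paste0(intervention$arm, " vs ", reference$arm),
    delta_cost = dc, delta_qalys = dq, delta_ly = dl,
    icer = if (label == "ICER") dc / dq else NA_real_,
    label = label
  ), class = "copd_incremental")
}

#' @export
print.copd_incremental <- function(x, ...) {
  cat(sprintf("%s: Δcost %.0f SEK, ΔQALY %.4f, ΔLY %.4f -> %s\n",
              x$comparison, x$delta_cost, x$delta_qalys, x$delta_ly,
              if (x$label == "ICER") sprintf("ICER %.0f SEK/QALY", x$icer) else x$label))
  invisible(x)
}

#' Net monetary benefit at a willingness-to-pay threshold
#'
#' `NMB = WTP * delta_QALY - delta_cost`; positive iff the intervention is
#' cost-effective at that threshold. Linear in WTP and zero exactly at
#' `WTP = ICER` when QALYs are gained.
#'
#' @param inc A `copd_incremental`.
#' @param wtp Willingness to pay, SEK per QALY (>= 0).
#' @return List with `wtp` and `nmb` (SEK).
#' @export
net_monetary_benefit <- function(inc, wtp) {
  stopifnot(inherits(inc, "copd_incremental"))
  if (any(wtp < 0)) stop("willingness to pay must be >= 0")
  list(wtp = wtp, nmb = wtp * inc$delta_qalys - inc$delta_cost)
}

#' Tabulate base-case arm results
#'
#' Arranges a set of arm results into the conventional cost-effectiveness
#' report layout: one column per arm plus a difference column per
#' intervention against the reference, rows for treatment costs, other
#' direct costs, total costs, QALYs and life years, with the ICER appended.
#'
#' @param results Named list of `copd_arm_result` objects; the first is the
#'   reference.
#' @return A data frame.
#' @export
comparison_table <- function(results) {
  stopifnot(length(results) >= 2)
  rows <- c("treatment_cost", "other_direct_cost", "total_cost", "qalys", "life_years")
  out <- data.frame(row.names = c("Treatment costs", "Direct costs", "Total costs",
                                  "QALYs", "Life years", "ICER"))
  ref <- results[[1]]
  for (res in results) {
    out[[res$arm]] <- c(unlist(res[rows]), NA)
  }
  for (res in results[-1]) {
    inc <- incremental_analysis(ref, res)
    out[[paste0(res$arm, "-", ref$arm)]] <-
      c(res$treatment_cost - ref$treatment_cost,
        res$other_direct_cost - ref$other_direct_cost,
        inc$delta_cost, inc$delta_qalys, inc$delta_ly,
        if (inc$label == "ICER") inc$icer else NA)
  }
  out
}
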