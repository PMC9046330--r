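#' Net monetary benefit
#'
#' `nmb = wtp * total_qalys - total_cost`, linear in all three arguments.
#'
#' @param total_cost Discounted total cost (AUD).
#' @param total_qalys Discounted total QALYs.
#' @param wtp Willingness-to-pay threshold (AUD per QALY), non-negative.
#' @return Net monetary benefit in AUD.
#' @export
nmb <- function(total_cost, total_qalys, wtp) {
  if (any(wtp < 0)) stop("wtp must be non-negative")
  wtp * total_qalys - total_cost
}

#' Compare two cohort traces into a cost-utility result
#'
#' Aggregates the control and intervention traces into per-arm totals,
#' increments (intervention minus control), net monetary benefits, the
#' incremental NMB, and a dominance classification. The ICER is reported as a
#' number only in the trade-off quadrants; when one arm dominates it is
#' suppressed and flagged, since a negative cost-per-QALY ratio is not
#' interpretable.
#'
#' @param trace_control,trace_intervention `cohort_trace` objects from
#'   [run_cohort()] sharing the same horizon and cycle length.
#' @param wtp Willingness-to-pay threshold (AUD per QALY); defaults to the
#'   threshold carried by the traces.
#' @return An object of class `cua_result`: per-arm cost/QALYs/NMB,
#'   `delta_cost`, `delta_qalys`, `inmb`, `icer` (NA when dominated/dominant),
#'   and `dominance` in `{"intervention_dominant", "control_dominant",
#'   "trade_off"}`.
#' @export
compare_arms <- function(trace_control, trace_intervention, wtp = NULL) {
  stopifnot(inherits(trace_control, "cohort_trace"),
            inherits(trace_intervention, "cohort_trace"))
  if (trace_control$n_cycles != trace_intervention$n_cycles ||
      trace_control$cycle_months != trace_intervention$cycle_months)
    stop("incompatible traces: horizons or cycle lengths differ")
  if (is.null(wtp)) wtp <- trace_control$wtp

  arm_result <- function(tr) list(
    arm = tr$arm,
    total_cost = tr$total_cost,
    total_qalys = tr$total_qalys,
    nmb = nmb(tr$total_cost, tr$total_qalys, wtp)
  )
  ctl <- arm_result(trace_control)
  int <- arm_result(trace_intervention)
  d_cost <- int$total_cost - ctl$total_cost
  d_qaly <- int$total_qalys - ctl$total_qalys

  dominance <- if (d_cost < 0 && d_qaly > 0) "intervention_dominant"
    else if (d_cost > 0 && d_qaly < 0) "control_dominant"
    else "trade_off"
  icer <- if (dominance == "trade_off" && d_qaly != 0) d_cost / d_qaly
    else NA_real_

  structure(list(
    control = ctl, intervention = int,
    delta_cost = d_cost, delta_qalys = d_qaly,
    inmb = nmb(d_cost, d_qaly, wtp),
    icer = icer, dominance = dominance, wtp = wtp
  ), class = "cua_result")
}

#' Run the full base-case comparison for a parameter set
#'
#' Convenience wrapper: runs both arms through [run_cohort()] and compares
#' them with [compare_arms()].
#'
#' @param params An `adt_params` parameter set.
#' @return A `cua_result`.
#' @export
run_cua <- function(params) {
  compare_arms(run_cohort(params, "control"),
               run_cohort(params, "intervention"),
               wtp = params$wtp)
}

#' Tabulate a cost-utility result
#'
#' Mirrors the usual published layout: one row per arm plus an incremental
#' row, with discounted cost, QALYs, NMB and the dominance flag. Currency is
#' rounded to whole dollars and QALYs to two decimals for display only;
#' internal fields keep full precision.
#'
#' @param result A `cua_result`.
#' @param digits_qaly Decimal places for the QALY column (default 2).
#' @return A tibble.
#' @export
cua_table <- function(result, digits_qaly = 2) {
  stopifnot(inherits(result, "cua_result"))
  tibble::tibble(
    group = c("control", "intervention", "difference"),
    cost = round(c(result$control$total_cost, result$intervention$total_cost,
                   result$delta_cost)),
    qalys = round(c(result$control$total_qalys,
                    result$intervention$total_qalys,
                    result$delta_qalys), digits_qaly),
    nmb = round(c(result$control$nmb, result$intervention$nmb, result$inmb)),
    icer = c(NA, NA, if (is.na(result$icer)) NA else round(result$icer)),
    dominance = c(NA, NA, result$dominance)
  )
}

#' @export
print.cua_result <- function(x, ...) {
  cat(sprintf("Cost-utility comparison at WTP $%s/QALY\n",
              format(x$wtp, big.mark = ",")))
  cat(sprintf("  control:      cost $%8.0f  QALYs %.4f  NMB $%8.0f\n",
              x$control$total_cost, x$control$total_qalys, x$control$nmb))
  cat(sprintf("  intervention: cost $%8.0f  QALYs %.4f  NMB $%8.0f\n",
              x$intervention$total_cost, x$intervention$total_qalys,
              x$intervention$nmb))
  cat(sprintf("  increments:   dC $%.0f  dE %.4f QALYs  iNMB $%.0f\n",
              x$delta_cost, x$delta_qalys, x$inmb))
  cat("  dominance: ", x$dominance,
      if (!is.na(x$icer)) sprintf(" (ICER $%.0f/QALY)", x$icer) else "", "\n",
      sep = "")
  invisible(x)
}
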