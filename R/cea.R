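# Economic endpoints: incremental cost-effectiveness ratios, dominance
# classification, net monetary benefit, and willingness-to-pay verdicts.

#' Incremental cost-effectiveness of a comparator versus a reference strategy
#'
#' Computes incremental cost and effectiveness (comparator minus reference)
#' on unrounded totals and classifies dominance before any division: a
#' comparator that is cheaper and more effective is `dominant`, costlier and
#' less effective is `dominated`; the ICER is reported only when incremental
#' effectiveness is non-zero.
#'
#' @param reference A `run_result` for the reference strategy (here
#'   enalapril).
#' @param comparator A `run_result` for the comparator strategy.
#' @return An object of class `icer_result`: `d_cost`, `d_effect` (QALY),
#'   `d_ly`, `icer` (USD/QALY, `NA` when undefined), and `classification`
#'   (`"icer"`, `"dominant"`, `"dominated"`, `"equivalent"` or
#'   `"undefined"`).
#' @export
compute_icer <- function(reference, comparator) {
  stopifnot(inherits(reference, "run_result"),
            inherits(comparator, "run_result"))
  d_cost <- comparator$cost - reference$cost
  d_effect <- comparator$qaly - reference$qaly
  d_ly <- comparator$ly - reference$ly
  classification <-
    if (d_effect == 0 && d_cost == 0) "equivalent"
    else if (d_effect == 0) "undefined"
    else if (d_cost <= 0 && d_effect > 0) "dominant"
    else if (d_cost >= 0 && d_effect < 0) "dominated"
    else "icer"
  icer <- if (classification == "icer") d_cost / d_effect else NA_real_
  structure(
    list(reference = reference$strategy, comparator = comparator$strategy,
         d_cost = d_cost, d_effect = d_effect, d_ly = d_ly,
         icer = icer, classification = classification),
    class = "icer_result"
  )
}

#' Net monetary benefit of a strategy run
#'
#' `NMB = wtp * QALY - cost`.  The difference in NMB between two strategies
#' changes sign exactly at their pairwise ICER when the incremental
#' effectiveness is positive.
#'
#' @param result A `run_result`.
#' @param wtp Willingness-to-pay threshold, USD per QALY (non-negative).
#' @return Net monetary benefit in USD.
#' @export
net_monetary_benefit <- function(result, wtp) {
  stopifnot(inherits(result, "run_result"))
  if (wtp < 0) stop("`wtp` must be non-negative")
  wtp * result$qaly - result$cost
}

#' Willingness-to-pay verdict for an incremental comparison
#'
#' The comparator is judged cost-effective if it dominates the reference, or
#' if incremental effectiveness is positive and the ICER lies strictly below
#' the threshold.
#'
#' @param icer An [compute_icer()] result.
#' @param wtp Willingness-to-pay threshold, USD per QALY (positive).
#' @return `TRUE` if cost-effective at the threshold, else `FALSE`.
#' @export
wtp_verdict <- function(icer, wtp) {
  stopifnot(inherits(icer, "icer_result"))
  if (wtp <= 0) stop("`wtp` must be positive")
  if (icer$classification == "dominant") return(TRUE)
  if (icer$classification != "icer" || icer$d_effect <= 0) return(FALSE)
  icer$icer > 0 && icer$icer < wtp
}

#' Base-case results table with the event/occupancy decomposition
#'
#' Assembles a results table mirroring the standard base-case layout: one row
#' per strategy with total discounted cost, QALY and LY, plus two
#' decomposition rows - "HF hospitalization" (event-based accruals: the
#' hospitalization cost and the per-event utility decrement, carrying no
#' life-years) and "Stable state" (occupancy-based accruals).  Incremental
#' columns and ICERs are computed against the first element of `runs`.
#'
#' @param runs Named list of `run_result` objects; the first is the
#'   reference strategy.
#' @return A data frame with columns `intervention`, `component`,
#'   `cost_usd`, `qaly`, `ly`, `inc_cost_usd`, `inc_qaly`, `icer_usd_per_qaly`.
#' @export
results_table <- function(runs) {
  stopifnot(length(runs) >= 1, all(vapply(runs, inherits, TRUE, "run_result")))
  ref <- runs[[1]]
  rows <- list()
  for (i in seq_along(runs)) {
    run <- runs[[i]]
    inc <- if (i == 1) NULL else compute_icer(ref, run)
    rows[[length(rows) + 1]] <- data.frame(
      intervention = run$strategy, component = "total",
      cost_usd = run$cost, qaly = run$qaly, ly = run$ly,
      inc_cost_usd = if (i == 1) NA_real_ else inc$d_cost,
      inc_qaly = if (i == 1) NA_real_ else inc$d_effect,
      icer_usd_per_qaly = if (i == 1) NA_real_ else inc$icer
    )
    rows[[length(rows) + 1]] <- data.frame(
      intervention = run$strategy, component = "HF hospitalization",
      cost_usd = run$cost_events, qaly = run$qaly_events, ly = 0,
      inc_cost_usd = if (i == 1) NA_real_ else run$cost_events - ref$cost_events,
      inc_qaly = if (i == 1) NA_real_ else run$qaly_events - ref$qaly_events,
      icer_usd_per_qaly = NA_real_
    )
    rows[[length(rows) + 1]] <- data.frame(
      intervention = run$strategy, component = "Stable state",
      cost_usd = run$cost_occupancy, qaly = run$qaly_occupancy, ly = run$ly,
      inc_cost_usd = if (i == 1) NA_real_ else run$cost_occupancy - ref$cost_occupancy,
      inc_qaly = if (i == 1) NA_real_ else run$qaly_occupancy - ref$qaly_occupancy,
      icer_usd_per_qaly = NA_real_
    )
  }
  do.call(rbind, rows)
}

#' @export
print.icer_result <- function(x, ...) {
  cat(sprintf("%s vs %s: dC %.1f USD, dE %.4f QALY", x$comparator,
              x$reference, x$d_cost, x$d_effect))
  if (x$classification == "icer") {
    cat(sprintf(", ICER %.1f USD/QALY\n", x$icer))
  } else {
    cat(sprintf(" (%s)\n", x$classification))
  }
  invisible(x)
}
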