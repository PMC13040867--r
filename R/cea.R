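#' Incremental cost-effectiveness comparison of two arms
#'
#' Computes per-arm totals and the incremental cost and QALY of the
#' perioperative (comparator) arm versus the adjuvant (reference) arm, and
#' classifies the result: higher QALY at lower cost is cost-saving
#' dominance, higher QALY at higher cost yields an ICER
#' (`delta cost / delta QALY`) judged against the willingness-to-pay
#' threshold, and lower QALY at higher cost is dominated. Internal
#' arithmetic is kept at full precision; rounding is left to the reporting
#' helpers.
#'
#' @param comparator,reference `perio_trace` objects (aggregate arm traces);
#'   increments are comparator minus reference.
#' @param wtp Willingness-to-pay threshold in USD per QALY.
#' @return Object of class `perio_cea`: list with `arms` (per-arm totals and
#'   cost breakdown), `delta_cost`, `delta_qaly`, `icer` (NA when not
#'   defined), `verdict` (`"cost_saving_dominant"`, `"icer"` or
#'   `"dominated"`), `cost_effective` and `wtp`.
#' @export
compare_arms <- function(comparator, reference, wtp = 1e5) {
  stopifnot(inherits(comparator, "perio_trace"), inherits(reference, "perio_trace"))
  dc <- comparator$total_cost - reference$total_cost
  dq <- comparator$qaly - reference$qaly
  if (dq > 0 && dc <= 0) {
    verdict <- "cost_saving_dominant"; icer <- NA_real_; ce <- TRUE
  } else if (dq > 0 && dc > 0) {
    verdict <- "icer"; icer <- dc / dq; ce <- icer < wtp
  } else if (dq < 0 && dc >= 0) {
    verdict <- "dominated"; icer <- NA_real_; ce <- FALSE
  } else if (dq < 0 && dc < 0) {
    # comparator cheaper but less effective: ICER of the forgone benefit
    verdict <- "icer"; icer <- dc / dq; ce <- icer > wtp
  } else {
    # dq == 0: verdict by cost sign alone, no ICER
    verdict <- if (dc < 0) "cost_saving_dominant" else
      if (dc > 0) "dominated" else "icer"
    icer <- NA_real_; ce <- dc <= 0
  }
  structure(list(
    arms = list(comparator = arm_summary(comparator),
                reference = arm_summary(reference)),
    delta_cost = dc, delta_qaly = dq,
    delta_ly = comparator$ly_disc - reference$ly_disc,
    icer = icer, verdict = verdict, cost_effective = ce, wtp = wtp
  ), class = "perio_cea")
}

arm_summary <- function(trace) {
  list(arm_id = trace$arm_id, cost = trace$cost, total_cost = trace$total_cost,
       qaly = trace$qaly, ly_disc = trace$ly_disc, ly_undisc = trace$ly_undisc)
}

#' Incremental net monetary benefit
#'
#' `wtp * delta QALY - delta cost`; positive means the comparator is
#' cost-effective at that threshold.
#'
#' @param result A `perio_cea` object.
#' @param wtp Willingness-to-pay, USD per QALY, vectorised.
#' @return Numeric vector of incremental net monetary benefit in USD.
#' @export
net_monetary_benefit <- function(result, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * result$delta_qaly - result$delta_cost
}

#' Table-shaped summary of a comparison
#'
#' One row per arm mirroring the published base-case table: total cost, the
#' three perioperative-phase cost columns, cost before and after recurrence,
#' QALY and (discounted) life-years, plus the incremental columns on the
#' comparator row. Money is rounded to whole USD, QALY/LY to two decimals.
#'
#' @param result A `perio_cea` object.
#' @return Data frame.
#' @export
cea_table <- function(result) {
  row <- function(a, inc = FALSE) {
    data.frame(
      strategy = a$arm_id,
      total_cost = round(a$total_cost),
      cost_neoadjuvant = round(a$cost[["neoadjuvant"]]),
      cost_surgery = round(a$cost[["surgery"]]),
      cost_adjuvant = round(a$cost[["adjuvant"]]),
      cost_before_recurrence = round(a$cost[["before_recurrence"]]),
      cost_after_recurrence = round(a$cost[["after_recurrence"]]),
      qaly = round(a$qaly, 2),
      ly = round(a$ly_disc, 2),
      incremental_cost = if (inc) round(result$delta_cost) else NA_real_,
      incremental_qaly = if (inc) round(result$delta_qaly, 2) else NA_real_,
      icer = if (!inc) NA_character_ else if (result$verdict == "cost_saving_dominant")
        "Cost-saving" else if (result$verdict == "dominated") "Dominated" else
          sprintf("%.0f", result$icer),
      stringsAsFactors = FALSE)
  }
  rbind(row(result$arms$reference), row(result$arms$comparator, inc = TRUE))
}

#' @export
print.perio_cea <- function(x, ...) {
  cat(sprintf(
    "<perio_cea> %s vs %s\n  dCost %.0f USD, dQALY %.3f -> %s%s (WTP %.0f)\n",
    x$arms$comparator$arm_id, x$arms$reference$arm_id,
    x$delta_cost, x$delta_qaly, x$verdict,
    if (is.na(x$icer)) "" else sprintf(" (ICER %.0f USD/QALY)", x$icer),
    x$wtp))
  invisible(x)
}
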