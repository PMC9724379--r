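#' Net monetary benefit
#'
#' `NMB = expected QALYs * wtp - expected cost`: the value of a strategy in
#' monetary terms at a willingness-to-pay threshold `wtp` per QALY.
#'
#' @param outcome a `cua_outcome` from [rollback()] (or any list with
#'   `cost` and `qaly` components).
#' @param wtp willingness-to-pay threshold per QALY (>= 0).
#' @return Net monetary benefit in the cost currency.
#' @examples
#' nmb(list(cost = 404.40, qaly = 0.924608), wtp = 5180)
#' @export
nmb <- function(outcome, wtp) {
  if (!is.numeric(wtp) || length(wtp) != 1L || wtp < 0)
    stop("wtp must be a single non-negative number")
  outcome$qaly * wtp - outcome$cost
}

#' Incremental comparison of two strategies
#'
#' Computes incremental cost and QALYs (`intervention - reference`), the
#' dominance verdict, the ICER when it is meaningful, per-strategy net
#' monetary benefit and the incremental net monetary benefit
#' `INMB = dQALY * wtp - dCost`.
#'
#' Dominance is detected before any ratio is formed: the intervention is
#' `dominant` iff it is strictly cheaper and strictly more effective
#' (negative `delta_cost`, positive `delta_qaly`), `dominated` in the
#' mirror case. In those quadrants a cost-per-QALY ratio is misleading, so
#' `icer_value` is withheld (`NA`). Otherwise the status is `ratio` with
#' `icer_value = delta_cost / delta_qaly`; a zero QALY difference leaves
#' the ratio undefined (`NA`) with `icer_note` flagging it.
#'
#' @param reference,intervention `cua_outcome` objects (see [rollback()]).
#' @param wtp willingness-to-pay threshold per QALY.
#' @return A `cua_comparison`: strategies, per-strategy cost/QALY/NMB,
#'   `delta_cost`, `delta_qaly`, `icer_status`
#'   (`"dominant"`/`"dominated"`/`"ratio"`), `icer_value`, `icer_note`,
#'   `inmb`, `wtp`.
#' @examples
#' pl <- list(strategy = "placebo", cost = 404.40, qaly = 0.924608)
#' om <- list(strategy = "om85",    cost = 215.54, qaly = 0.934613)
#' compare_strategies(pl, om, wtp = 5180)
#' @export
compare_strategies <- function(reference, intervention, wtp) {
  if (identical(reference$strategy, intervention$strategy) &&
      !is.null(reference$strategy))
    stop("reference and intervention must be distinct strategies")
  dc <- intervention$cost - reference$cost
  dq <- intervention$qaly - reference$qaly
  nmb_ref <- nmb(reference, wtp)
  nmb_int <- nmb(intervention, wtp)

  status <- if (dc < 0 && dq > 0) "dominant"
            else if (dc > 0 && dq < 0) "dominated"
            else "ratio"
  icer <- NA_real_
  note <- NA_character_
  if (status == "ratio") {
    if (dq == 0) note <- "ICER undefined: zero QALY difference"
    else icer <- dc / dq
  } else {
    note <- paste0("ICER withheld under ", status, " intervention")
  }
  structure(list(
    reference = reference$strategy %||% "reference",
    intervention = intervention$strategy %||% "intervention",
    cost_reference = reference$cost, qaly_reference = reference$qaly,
    cost_intervention = intervention$cost, qaly_intervention = intervention$qaly,
    delta_cost = dc, delta_qaly = dq,
    icer_status = status, icer_value = icer, icer_note = note,
    nmb_reference = nmb_ref, nmb_intervention = nmb_int,
    inmb = dq * wtp - dc, wtp = wtp),
    class = "cua_comparison")
}

#' Tabulate a comparison
#'
#' Two-row table (reference first) in the layout cost-utility studies
#' print: strategy, expected cost, incremental cost, expected QALYs,
#' incremental QALYs, NMB. Costs and QALYs are rounded to 2 decimals for
#' display; the underlying comparison object keeps full precision.
#'
#' @param x a `cua_comparison`.
#' @param digits decimals used for rounding (default 2).
#' @return `data.frame` with one row per strategy.
#' @export
comparison_table <- function(x, digits = 2) {
  stopifnot(inherits(x, "cua_comparison"))
  data.frame(
    strategy = c(x$reference, x$intervention),
    cost = round(c(x$cost_reference, x$cost_intervention), digits),
    delta_cost = c(NA, round(x$delta_cost, digits)),
    qaly = round(c(x$qaly_reference, x$qaly_intervention), digits),
    delta_qaly = c(NA, round(x$delta_qaly, digits)),
    nmb = round(c(x$nmb_reference, x$nmb_intervention), digits),
    stringsAsFactors = FALSE)
}

#' @export
print.cua_comparison <- function(x, ...) {
  cat(sprintf("Cost-utility comparison (WTP %s per QALY)\n",
              format(x$wtp, big.mark = ",")))
  print(comparison_table(x), row.names = FALSE)
  verdict <- switch(x$icer_status,
    dominant  = sprintf("'%s' dominates '%s' (cheaper and more effective)",
                        x$intervention, x$reference),
    dominated = sprintf("'%s' is dominated by '%s'", x$intervention, x$reference),
    ratio     = if (is.na(x$icer_value)) x$icer_note
                else sprintf("ICER = %.2f per QALY", x$icer_value))
  cat(verdict, "\n")
  cat(sprintf("INMB at WTP: %.2f\n", x$inmb))
  invisible(x)
}
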