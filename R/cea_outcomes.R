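#' Incremental cost-effectiveness ratio and dominance
#'
#' Computes exact increments between two strategies, classifies dominance
#' (weakly lower cost and higher effect, excluding the both-zero case), and
#' forms the ICER only when the effect difference is non-zero. Net monetary
#' benefit at the supplied willingness-to-pay is attached.
#'
#' @param intervention,comparator `strategy_result` objects (or lists with
#'   `cost` and `qaly`) computed on the same horizon and discounting.
#' @param wtp Willingness-to-pay threshold, dollars per QALY.
#' @return A `ce_result`: list with `dcost`, `deffect`, `icer` (`NA` when
#'   undefined), `nmb`, `status` (`"ICER"`, `"dominant"`, `"dominated"`,
#'   `"equivalent"`) and `cost_effective`.
#' @export
icer <- function(intervention, comparator, wtp = NA_real_) {
  dc <- intervention$cost - comparator$cost
  de <- intervention$qaly - comparator$qaly
  status <- if (dc == 0 && de == 0) "equivalent"
    else if (dc <= 0 && de >= 0) "dominant"
    else if (dc >= 0 && de <= 0) "dominated"
    else "ICER"
  ratio <- if (de != 0) dc / de else NA_real_
  nmb <- if (is.na(wtp)) NA_real_ else wtp * de - dc
  ce <- switch(status,
    dominant = TRUE,
    dominated = FALSE,
    equivalent = NA,
    ICER = if (is.na(wtp)) NA else (de > 0 && ratio < wtp))
  structure(list(dcost = dc, deffect = de, icer = ratio, nmb = nmb,
                 wtp = wtp, status = status, cost_effective = ce),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf(paste0("<ce_result> dCost $%.2f | dQALY %.4f | %s"),
              x$dcost, x$deffect, x$status))
  if (!is.na(x$icer)) cat(sprintf(" | ICER $%.2f/QALY", x$icer))
  if (!is.na(x$nmb)) cat(sprintf(" | NMB $%.2f at WTP $%s", x$nmb,
                                 format(x$wtp, big.mark = ",")))
  cat("\n")
  invisible(x)
}

#' Net monetary benefit
#'
#' `NMB = WTP * dEffect - dCost`; positive exactly when the intervention is
#' cost-effective at that threshold (for a positive effect difference this
#' is equivalent to ICER < WTP).
#'
#' @param result A [icer()] result (or list with `dcost`, `deffect`).
#' @param wtp Willingness-to-pay (>= 0), dollars per QALY.
#' @return Dollars.
#' @export
net_monetary_benefit <- function(result, wtp) {
  if (wtp < 0) stop("wtp must be >= 0")
  wtp * result$deffect - result$dcost
}

#' Base-case results table
#'
#' Two-row table mirroring the conventional base-case layout: strategy,
#' total cost, incremental cost, life-years, QALYs, incremental
#' effectiveness, ICER.
#'
#' @param intervention,comparator `strategy_result` objects.
#' @param ce The matching [icer()] result.
#' @return A data frame.
#' @export
results_table <- function(intervention, comparator, ce) {
  data.frame(
    strategy = c(intervention$label, comparator$label),
    cost = round(c(intervention$cost, comparator$cost), 2),
    incremental_cost = c(round(ce$dcost, 2), NA),
    ly = round(c(intervention$ly, comparator$ly), 2),
    qaly = round(c(intervention$qaly, comparator$qaly), 2),
    incremental_effectiveness = c(round(ce$deffect, 2), NA),
    icer = c(round(ce$icer, 2), NA))
}
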