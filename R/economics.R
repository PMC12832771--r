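DAYS_PER_CYCLE <- 365.25 / 12   # one model cycle in days

#' Discount factor for a monthly cycle index
#'
#' End-of-cycle convention on an annual rate: `(1 + r)^(-t/12)` for cycle
#' `t`.
#'
#' @param r Annual discount rate (>= 0).
#' @param t Cycle index (months); vectorized.
#' @return Discount factor(s) in (0, 1].
#' @export
discount_factor <- function(r, t) {
  if (any(r < 0)) stop("discount rate must be >= 0")
  (1 + r)^(-t / 12)
}

#' Drug administration schedule
#'
#' A schedule is a list of components, one per drug/phase. Each component is
#' built with [drug_component()]: intravenous drugs dose per administration
#' (per-kg or flat mg) on a fixed day interval with an optional dose cap
#' (induction) and start day (maintenance); oral drugs dose continuously in
#' mg/day. `share` scales a component by the fraction of the arm receiving
#' it, which represents investigator's-choice arms as a cost-weighted blend.
#'
#' @param ... `drug_component` objects.
#' @return An object of class `drug_schedule`.
#' @export
drug_schedule <- function(...) {
  comps <- list(...)
  if (!length(comps)) stop("schedule needs at least one component")
  for (comp in comps) stopifnot(inherits(comp, "drug_component"))
  structure(comps, class = "drug_schedule")
}

#' @rdname drug_schedule
#' @param drug Price-list name of the drug.
#' @param rule `"per_kg"` (mg/kg per administration), `"flat"` (mg per
#'   administration) or `"daily"` (mg per day, oral).
#' @param dose Dose in the rule's unit (> 0).
#' @param interval_days Days between administrations (iv rules; > 0).
#' @param start_day First administration day (default 0).
#' @param max_doses Cap on administrations across the whole course
#'   (default unlimited).
#' @param route `"iv"` (accrues administration costs) or `"oral"`.
#' @param share Fraction of the arm receiving this component, in [0, 1].
#' @param vial_size_mg Optional vial size: each administration's mg is
#'   rounded up to a whole number of vials (wastage). Default no rounding.
#' @param max_days Optional cap on treatment duration in days from
#'   `start_day` (daily rules; per-administration rules cap via
#'   `max_doses`).
#' @export
drug_component <- function(drug, rule = c("per_kg", "flat", "daily"), dose,
                           interval_days = NA, start_day = 0,
                           max_doses = Inf, route = c("iv", "oral"),
                           share = 1, vial_size_mg = NA, max_days = Inf) {
  rule <- match.arg(rule)
  route <- match.arg(route)
  if (dose <= 0) stop("dose must be > 0")
  if (rule != "daily" && (is.na(interval_days) || interval_days <= 0))
    stop("interval_days must be > 0 for per-administration rules")
  if (share < 0 || share > 1) stop("share must be in [0, 1]")
  if (!is.na(vial_size_mg) && vial_size_mg <= 0)
    stop("vial_size_mg must be > 0")
  structure(list(drug = drug, rule = rule, dose = dose,
                 interval_days = interval_days, start_day = start_day,
                 max_doses = max_doses, route = route, share = share,
                 vial_size_mg = vial_size_mg, max_days = max_days),
            class = "drug_component")
}

# administrations of one component falling inside cycle `cycle_index`
# (cycle t covers days [(t-1), t) * DAYS_PER_CYCLE)
doses_in_cycle <- function(comp, cycle_index) {
  if (comp$rule == "daily") return(0L)
  lo <- (cycle_index - 1) * DAYS_PER_CYCLE
  hi <- cycle_index * DAYS_PER_CYCLE
  kmax <- if (is.finite(comp$max_doses)) comp$max_doses - 1 else
    ceiling((hi - comp$start_day) / comp$interval_days) + 1
  if (kmax < 0) return(0L)
  days <- comp$start_day + comp$interval_days * (0:kmax)
  sum(days >= lo & days < hi)
}

#' First-line drug acquisition cost for one cycle
#'
#' Converts each schedule component's dosing rule to mg consumed inside the
#' one-month cycle (`365.25/12` days) and multiplies by the per-mg price.
#' Administration caps are respected across cycles, so an induction ->
#' maintenance switch falls out of the schedule itself.
#'
#' @param schedule A [drug_schedule()].
#' @param weight_kg Mean body weight (> 0), used by per-kg rules.
#' @param prices Named list/vector of per-mg prices covering every component.
#' @param cycle_index Cycle number (1-based).
#' @return Drug cost in dollars for the cycle.
#' @export
drug_cost_per_cycle <- function(schedule, weight_kg, prices, cycle_index) {
  if (weight_kg <= 0) stop("weight_kg must be > 0")
  total <- 0
  for (comp in schedule) {
    price <- prices[[comp$drug]]
    if (is.null(price)) stop("no price configured for drug '", comp$drug, "'")
    if (comp$rule == "daily") {
      # days of this cycle falling inside the component's treatment window
      lo <- (cycle_index - 1) * DAYS_PER_CYCLE
      hi <- cycle_index * DAYS_PER_CYCLE
      days <- max(0, min(hi, comp$start_day + comp$max_days) -
                    max(lo, comp$start_day))
      mg <- comp$dose * days
    } else {
      per_admin <- if (comp$rule == "per_kg") comp$dose * weight_kg
                   else comp$dose
      if (!is.na(comp$vial_size_mg))
        per_admin <- ceiling(per_admin / comp$vial_size_mg) * comp$vial_size_mg
      mg <- doses_in_cycle(comp, cycle_index) * per_admin
    }
    total <- total + mg * price * comp$share
  }
  total
}

# infusion count for administration costs (oral components contribute none)
infusions_per_cycle <- function(schedule, cycle_index) {
  sum(vapply(schedule, function(comp)
    if (comp$route == "iv") doses_in_cycle(comp, cycle_index) * comp$share
    else 0, numeric(1)))
}

#' Standard first-line schedules
#'
#' `schedule_nivo_ipi()`: nivolumab 1 mg/kg + ipilimumab 3 mg/kg every
#' 3 weeks for up to four doses, then maintenance nivolumab 480 mg flat
#' every 4 weeks (starting one maintenance interval after the last
#' induction dose). `schedule_comparator()`: a share-weighted blend of
#' lenvatinib (8 mg/day under 60 kg, 12 mg/day at 60 kg and over, mixed by
#' `prop_weight_ge60`) and sorafenib 400 mg twice daily.
#'
#' @return A [drug_schedule()].
#' @export
schedule_nivo_ipi <- function() {
  drug_schedule(
    drug_component("nivolumab", "per_kg", 1, interval_days = 21,
                   max_doses = 4, route = "iv"),
    drug_component("ipilimumab", "per_kg", 3, interval_days = 21,
                   max_doses = 4, route = "iv"),
    drug_component("nivolumab", "flat", 480, interval_days = 28,
                   start_day = 3 * 21 + 28, route = "iv"))
}

#' @rdname schedule_nivo_ipi
#' @param len_share Fraction of the arm on lenvatinib (remainder sorafenib).
#' @param prop_weight_ge60 Fraction dosed at the 12 mg lenvatinib tier.
#' @export
schedule_comparator <- function(len_share = 0.85, prop_weight_ge60 = 0.70) {
  len_dose <- 12 * prop_weight_ge60 + 8 * (1 - prop_weight_ge60)
  comps <- list()
  if (len_share > 0)
    comps <- c(comps, list(drug_component("lenvatinib", "daily", len_dose,
                                          route = "oral", share = len_share)))
  if (len_share < 1)
    comps <- c(comps, list(drug_component("sorafenib", "daily", 800,
                                          route = "oral",
                                          share = 1 - len_share)))
  do.call(drug_schedule, comps)
}

#' Weighted monthly cost of subsequent systemic therapy
#'
#' The weighted mean of regimen-specific monthly costs over the proportions
#' of patients receiving each subsequent regimen; patients without
#' subsequent antitumor therapy (the remainder) are costed at the best
#' supportive care rate.
#'
#' @param proportions Proportions per regimen (sum <= 1).
#' @param monthly_costs Monthly cost per regimen, same length/order.
#' @param bsc_monthly Best-supportive-care monthly cost for the remainder.
#' @return Dollars per cycle.
#' @export
weighted_subsequent_cost <- function(proportions, monthly_costs,
                                     bsc_monthly = 0) {
  stopifnot(length(proportions) == length(monthly_costs))
  if (any(proportions < 0)) stop("proportions must be >= 0")
  if (sum(proportions) > 1 + 1e-9) stop("proportions must sum to <= 1")
  sum(proportions * monthly_costs) + (1 - sum(proportions)) * bsc_monthly
}

#' Discounted costs, QALYs and life-years on a state trace
#'
#' Accrual per cycle `t` (discounted by `(1+r)^(-t/12)`): first-line drug
#' and administration costs weighted by PFS occupancy (treatment to
#' progression), subsequent-therapy cost by PFS2 occupancy, best supportive
#' care by PD occupancy, follow-up by total alive occupancy, a one-time
#' end-of-life cost on incident deaths, and adverse-event management costs
#' once in cycle 1. QALYs accrue occupancy times state utility per cycle,
#' minus a one-time first-cycle adverse-event disutility
#' (`incidence * disutility * 1/12` years per event type).
#'
#' @param trace A [compute_occupancy()] state trace.
#' @param params An [make_parameter_set()] economic parameter set.
#' @param schedule First-line [drug_schedule()] for this arm.
#' @param arm `"intervention"` or `"comparator"` (selects adverse-event and
#'   subsequent-therapy inputs from `params`).
#' @param label Strategy label for the result.
#' @param half_cycle_correction Trapezoid accrual of occupancies.
#' @param pfs_only Restrict cost and QALY accrual to the PFS state
#'   (scenario analysis support).
#' @return A `strategy_result`: list with `label`, `cost`, `qaly`, `ly` and
#'   a `breakdown` of discounted cost categories (drug, administration, AE,
#'   follow-up, subsequent, BSC, end-of-life) summing to the total.
#' @export
accumulate <- function(trace, params, schedule,
                       arm = c("intervention", "comparator"),
                       label = arm, half_cycle_correction = FALSE,
                       pfs_only = FALSE) {
  arm <- match.arg(arm)
  label <- if (identical(label, arm)) arm else label
  n <- nrow(trace) - 1
  r <- params$discount_rate
  t <- seq_len(n)
  df <- discount_factor(r, t)

  occ_pfs <- cycle_accrual(trace$pfs, half_cycle_correction)
  occ_pfs2 <- cycle_accrual(trace$pfs2, half_cycle_correction)
  occ_pd <- cycle_accrual(trace$pd, half_cycle_correction)
  if (pfs_only) {
    occ_pfs2 <- occ_pfs2 * 0
    occ_pd <- occ_pd * 0
  }
  occ_alive <- occ_pfs + occ_pfs2 + occ_pd
  inc_death <- trace$incident_deaths[-1]

  drug_c <- vapply(t, function(i)
    drug_cost_per_cycle(schedule, params$weight_kg, params$prices, i),
    numeric(1))
  admin_c <- vapply(t, function(i) infusions_per_cycle(schedule, i),
                    numeric(1)) * params$admin_cost_per_infusion

  sub <- params$subsequent[[arm]]
  sub_c <- weighted_subsequent_cost(sub$proportions, sub$monthly_costs,
                                    params$bsc_cost_per_cycle)
  ae <- params$ae[[arm]]

  breakdown <- c(
    drug = sum(occ_pfs * drug_c * df),
    administration = sum(occ_pfs * admin_c * df),
    ae = sum(ae$incidence * ae$cost) * df[1],
    followup = sum(occ_alive * params$followup_cost_per_cycle * df),
    subsequent = sum(occ_pfs2 * sub_c * df),
    bsc = sum(occ_pd * params$bsc_cost_per_cycle * df),
    eol = sum(inc_death * params$eol_cost * df))

  u <- params$utilities
  qaly <- sum((occ_pfs * u$pfs + occ_pfs2 * u$pfs2 + occ_pd * u$pd) * df) / 12 -
    sum(ae$incidence * ae$disutility) * (1 / 12) * df[1]
  ly <- sum(occ_alive * df) / 12

  structure(list(label = label, cost = sum(breakdown), qaly = qaly, ly = ly,
                 breakdown = breakdown),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result> %s: cost $%s | %.3f LY | %.3f QALY\n",
              x$label, format(round(x$cost, 2), big.mark = ","), x$ly, x$qaly))
  invisible(x)
}
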