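#' Describe a two-arm synthetic trial with known ground truth
#'
#' A `trial_scenario` holds everything needed to simulate a two-arm trial
#' emulating the structure of a first-line uHCC study: per-arm sample sizes,
#' the true parametric event-time distributions per endpoint, and the
#' administrative censoring pattern. Endpoint truths are given per arm as
#' parametric families (see [survival_function()] for parameterizations).
#'
#' Two generation modes are supported. With `correlate = TRUE` (default),
#' overall survival is constructed per subject as
#' `OS = PFS + post-progression survival`, with PFS and the post-progression
#' sojourn drawn from the `pfs` and `pps` truths; the subject-level ordering
#' `PFS <= OS` then holds by construction, matching strictly sequential
#' disease states. With `correlate = FALSE`, OS is drawn directly from the
#' `os` truth and PFS independently from the `pfs` truth, capped at OS.
#'
#' Administrative censoring: subjects enter uniformly over
#' `[0, accrual_window]` and the study is cut at `admin_censor_time` months
#' after the first enrolment, so each subject's potential follow-up is
#' `admin_censor_time - entry`. Set `accrual_window = 0` for a common cutoff.
#'
#' @param arm_names Character vector of two arm labels.
#' @param n_per_arm Integer vector of two positive per-arm sample sizes.
#' @param truth Named list (one entry per arm) of endpoint truths. Each arm's
#'   entry is a named list with elements `pfs` and either `pps` (correlated
#'   mode) or `os` (independent mode); each element is
#'   `list(family = <name>, params = <named numeric>)`.
#' @param correlate Logical; generate OS as PFS plus a post-progression
#'   sojourn (`TRUE`) or directly from the `os` truth (`FALSE`).
#' @param hazard_ratio_os Descriptive OS hazard ratio of the scenario
#'   (metadata only; not used in generation).
#' @param admin_censor_time Administrative cutoff in months (> 0).
#' @param accrual_window Accrual duration in months (>= 0, less than
#'   `admin_censor_time`).
#' @param risk_table_interval Spacing of number-at-risk grid points, months.
#' @param seed Integer seed stored with the scenario.
#' @return An object of class `trial_scenario`.
#' @seealso [simulate_ipd()], [default_scenario()]
#' @export
trial_scenario <- function(arm_names, n_per_arm, truth,
                           correlate = TRUE,
                           hazard_ratio_os = NA_real_,
                           admin_censor_time = 41.2,
                           accrual_window = 12,
                           risk_table_interval = 3,
                           seed = 1L) {
  stopifnot(length(arm_names) == 2L, length(n_per_arm) == 2L)
  if (any(n_per_arm <= 0) || any(n_per_arm != round(n_per_arm)))
    stop("n_per_arm must be positive integers")
  if (admin_censor_time <= 0) stop("admin_censor_time must be > 0")
  if (accrual_window < 0 || accrual_window >= admin_censor_time)
    stop("accrual_window must be in [0, admin_censor_time)")
  if (!all(arm_names %in% names(truth)))
    stop("truth must contain an entry for each arm")
  for (arm in arm_names) {
    tr <- truth[[arm]]
    if (is.null(tr$pfs)) stop("truth for arm '", arm, "' lacks a pfs entry")
    if (correlate && is.null(tr$pps))
      stop("correlated generation needs a pps entry for arm '", arm, "'")
    if (!correlate && is.null(tr$os))
      stop("independent generation needs an os entry for arm '", arm, "'")
    for (ep in tr) check_family(ep$family, ep$params)
  }
  structure(
    list(arm_names = arm_names, n_per_arm = as.integer(n_per_arm),
         truth = truth, correlate = correlate,
         hazard_ratio_os = hazard_ratio_os,
         admin_censor_time = admin_censor_time,
         accrual_window = accrual_window,
         risk_table_interval = risk_table_interval,
         seed = as.integer(seed)),
    class = "trial_scenario")
}

#' Default synthetic scenario emulating a first-line uHCC trial
#'
#' Mirrors the published structure of the CheckMate 9DW comparison of
#' nivolumab + ipilimumab versus lenvatinib/sorafenib: 335 vs 333 subjects
#' (intention-to-treat) or 98 vs 110 (China subgroup), exponential PFS with
#' medians 9.1 / 9.2 months, and exponential post-progression sojourns whose
#' medians (10.4979 / 7.8393 months) were solved so the correlated
#' OS = PFS + PPS construction has OS medians 23.7 / 20.6 months
#' (descriptive OS hazard ratio 0.79). Accrual over 12 months with an
#' administrative cutoff at 41.2 months gives a median follow-up of
#' 35.2 months.
#'
#' @param population `"ITT"` (335/333) or `"China"` (98/110 subgroup).
#' @param seed Integer seed stored with the scenario.
#' @return A `trial_scenario`.
#' @export
default_scenario <- function(population = c("ITT", "China"), seed = 1L) {
  population <- match.arg(population)
  n <- if (population == "ITT") c(335L, 333L) else c(98L, 110L)
  arms <- c("NIVO+IPI", "LEN/SOR")
  truth <- list(
    "NIVO+IPI" = list(
      pfs = list(family = "exponential", params = c(rate = log(2) / 9.1)),
      pps = list(family = "exponential", params = c(rate = log(2) / 10.4979))),
    "LEN/SOR" = list(
      pfs = list(family = "exponential", params = c(rate = log(2) / 9.2)),
      pps = list(family = "exponential", params = c(rate = log(2) / 7.8393))))
  trial_scenario(arms, n, truth, correlate = TRUE, hazard_ratio_os = 0.79,
                 admin_censor_time = 41.2, accrual_window = 12,
                 risk_table_interval = 3, seed = seed)
}

# family samplers by inverse-CDF, all time units in months
rfamily <- function(family, params, n) {
  check_family(family, params, generation = TRUE)
  u <- stats::runif(n)
  p <- as.list(params)
  switch(family,
    exponential = -log(u) / p$rate,
    weibull     = p$scale * (-log(u))^(1 / p$shape),
    gompertz    = log1p(-(p$shape / p$rate) * log(u)) / p$shape,
    lognormal   = exp(p$meanlog + p$sdlog * stats::qnorm(1 - u)),
    loglogistic = p$scale * (1 / u - 1)^(1 / p$shape))
}

psmcea_families <- c("exponential", "weibull", "gompertz", "lognormal",
                     "loglogistic")

# Domain check shared by generation and evaluation. The gompertz shape may be
# any real for evaluation/fitting (negative shape = decreasing hazard, a
# defective distribution with a cure fraction), but event-time generation
# requires a proper distribution, hence shape > 0 there.
check_family <- function(family, params, generation = FALSE) {
  needed <- switch(family,
    exponential = "rate",
    weibull     = c("shape", "scale"),
    gompertz    = c("shape", "rate"),
    lognormal   = c("meanlog", "sdlog"),
    loglogistic = c("shape", "scale"),
    stop("unknown parametric family: '", family, "'"))
  params <- unlist(params)
  if (!all(needed %in% names(params)))
    stop("family '", family, "' needs parameters: ",
         paste(needed, collapse = ", "))
  pos <- setdiff(needed, switch(family, lognormal = "meanlog",
                                gompertz = "shape", character(0)))
  if (any(!is.finite(params[needed])))
    stop("family '", family, "' parameters must be finite")
  if (any(params[pos] <= 0))
    stop("family '", family, "' parameters must be positive: ",
         paste(pos, collapse = ", "))
  if (generation && family == "gompertz" && params[["shape"]] <= 0)
    stop("gompertz event-time generation needs shape > 0 (non-positive ",
         "shape gives an improper 'cure' distribution)")
  invisible(TRUE)
}

#' Simulate individual patient data from a trial scenario
#'
#' Draws per-subject PFS and OS event times from the scenario's true
#' families, applies administrative censoring (uniform accrual, common
#' cutoff), and returns one row per subject per endpoint. The same
#' `(scenario, seed)` pair always yields identical output.
#'
#' @param scenario A [trial_scenario()].
#' @param seed Integer seed; defaults to the scenario's own.
#' @return A data frame with columns `arm`, `id`, `endpoint` (`"os"`/`"pfs"`),
#'   `time` (months, > 0) and `event` (1 event, 0 censored).
#' @export
simulate_ipd <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "trial_scenario"))
  set.seed(as.integer(seed))
  out <- lapply(seq_along(scenario$arm_names), function(i) {
    arm <- scenario$arm_names[i]
    n <- scenario$n_per_arm[i]
    tr <- scenario$truth[[arm]]
    pfs <- rfamily(tr$pfs$family, tr$pfs$params, n)
    if (scenario$correlate) {
      os <- pfs + rfamily(tr$pps$family, tr$pps$params, n)
    } else {
      os <- rfamily(tr$os$family, tr$os$params, n)
      pfs <- pmin(pfs, os)  # sequential states: progression precedes death
    }
    entry <- if (scenario$accrual_window > 0)
      stats::runif(n, 0, scenario$accrual_window) else rep(0, n)
    cutoff <- scenario$admin_censor_time - entry
    data.frame(
      arm = arm, id = seq_len(n),
      endpoint = rep(c("os", "pfs"), each = n),
      time = c(pmin(os, cutoff), pmin(pfs, cutoff)),
      event = as.integer(c(os <= cutoff, pfs <= cutoff)),
      stringsAsFactors = FALSE)
  })
  ipd <- do.call(rbind, out)
  rownames(ipd) <- NULL
  ipd
}

#' Published-style Kaplan-Meier inputs from simulated IPD
#'
#' Converts one arm/endpoint of IPD into the pair of artifacts a digitized
#' figure would provide: the product-limit survival curve evaluated at the
#' event times, and a number-at-risk table on a regular grid (subjects with
#' observed time at or beyond each grid point).
#'
#' @param ipd Data frame with columns `time` and `event` (a single
#'   arm/endpoint; subset first if needed).
#' @param risk_table_interval Grid spacing for the number-at-risk table,
#'   months.
#' @param arm,endpoint Labels attached to the returned curve.
#' @return A list with elements `curve` (a [digitized_curve()]) and `risk`
#'   (a [risk_table()]).
#' @export
km_from_ipd <- function(ipd, risk_table_interval = 3,
                        arm = "", endpoint = "") {
  if (nrow(ipd) == 0L) stop("ipd must contain at least one row")
  est <- km_estimate(ipd, arm = arm, endpoint = endpoint)
  # published curves are drawn out to the last follow-up time; carry the
  # final estimate forward so the curve spans censorings after the last event
  if (max(ipd$time) > max(est$time))
    est <- digitized_curve(c(est$time, max(ipd$time)),
                           c(est$survival, min(est$survival)),
                           arm = arm, endpoint = endpoint)
  # axis ticks cover the plotted range, as on a published figure
  grid <- seq(0, risk_table_interval * ceiling(max(ipd$time) /
                                                 risk_table_interval),
              by = risk_table_interval)
  risk <- risk_table(time = grid,
                     n_at_risk = vapply(grid, function(g) sum(ipd$time >= g),
                                        integer(1)))
  list(curve = est, risk = risk)
}

#' Country economic parameter set (synthetic placeholders)
#'
#' Returns a complete economic parameter set for the US or China payer
#' perspective. Utilities (0.84 progression-free, 0.76 second
#' progression-free, 0.68 progressive disease, 0 death), discount rates
#' (3% US, 5% China annually) and willingness-to-pay thresholds
#' ($150,000/QALY US; $39,933.67/QALY China, three times per-capita GDP) are
#' the published model inputs. All unit costs, adverse-event incidences and
#' disutilities are synthetic placeholders of realistic magnitude
#' (`synthetic = TRUE` in the metadata): the original unit-cost tables are
#' not reproduced here.
#'
#' Monetary values are 2024 US dollars. Drug prices are per mg; cycle-level
#' costs are per one-month model cycle.
#'
#' @param country `"US"` or `"China"`.
#' @return An object of class `econ_params` (a named list).
#' @export
make_parameter_set <- function(country = c("US", "China")) {
  country <- match.arg(country)
  common <- list(
    utilities = list(pfs = 0.84, pfs2 = 0.76, pd = 0.68, death = 0),
    prop_male = 0.82,
    len_prop = 0.85,        # share of comparator arm on lenvatinib (vs sorafenib)
    prop_weight_ge60 = 0.70 # share dosed at the 12 mg lenvatinib tier
  )
  params <- if (country == "US") list(
    country = "US",
    discount_rate = 0.03,
    wtp = 150000,
    weight_kg = 70,
    prices = list(nivolumab = 31.80, ipilimumab = 157.00,
                  lenvatinib = 68.70, sorafenib = 0.55),
    admin_cost_per_infusion = 144,
    followup_cost_per_cycle = 620,
    bsc_cost_per_cycle = 2100,
    eol_cost = 12500,
    subsequent = list(
      intervention = list(proportions = c(tki = 0.35, local = 0.10),
                          monthly_costs = c(tki = 18500, local = 6000)),
      comparator   = list(proportions = c(immunotherapy = 0.30, tki = 0.15),
                          monthly_costs = c(immunotherapy = 16800, tki = 18500))),
    ae = list(
      intervention = data.frame(
        name = c("ast_increase", "immune_hepatitis", "diarrhea"),
        incidence = c(0.07, 0.06, 0.03),
        cost = c(6500, 11000, 4200),
        disutility = c(0.07, 0.11, 0.06)),
      comparator = data.frame(
        name = c("hypertension", "hand_foot", "diarrhea"),
        incidence = c(0.12, 0.05, 0.04),
        cost = c(3800, 2600, 4200),
        disutility = c(0.05, 0.08, 0.06)))
  ) else list(
    country = "China",
    discount_rate = 0.05,
    wtp = 39933.67,
    weight_kg = 65,
    prices = list(nivolumab = 4.20, ipilimumab = 26.50,
                  lenvatinib = 1.90, sorafenib = 0.05),
    admin_cost_per_infusion = 35,
    followup_cost_per_cycle = 160,
    bsc_cost_per_cycle = 320,
    eol_cost = 2600,
    subsequent = list(
      intervention = list(proportions = c(tki = 0.40, local = 0.10),
                          monthly_costs = c(tki = 1350, local = 900)),
      comparator   = list(proportions = c(immunotherapy = 0.35, tki = 0.15),
                          monthly_costs = c(immunotherapy = 2200, tki = 1350))),
    ae = list(
      intervention = data.frame(
        name = c("ast_increase", "immune_hepatitis", "diarrhea"),
        incidence = c(0.07, 0.06, 0.03),
        cost = c(900, 1800, 600),
        disutility = c(0.07, 0.11, 0.06)),
      comparator = data.frame(
        name = c("hypertension", "hand_foot", "diarrhea"),
        incidence = c(0.12, 0.05, 0.04),
        cost = c(500, 350, 600),
        disutility = c(0.05, 0.08, 0.06)))
  )
  out <- c(params, common)
  attr(out, "synthetic") <- TRUE
  class(out) <- "econ_params"
  out
}

#' @export
print.econ_params <- function(x, ...) {
  cat("<econ_params> country:", x$country,
      "| discount:", x$discount_rate,
      "| WTP:", format(x$wtp, big.mark = ","), "USD/QALY\n")
  if (isTRUE(attr(x, "synthetic")))
    cat("  unit costs are synthetic placeholders (2024 USD)\n")
  invisible(x)
}
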