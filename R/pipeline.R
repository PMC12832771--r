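#' Read and write pipeline CSV artifacts
#'
#' Plain-CSV schemas shared across the pipeline: digitized curves
#' (`time_months`, `survival`), number-at-risk tables (`time_months`,
#' `n_at_risk`) and individual patient data (`time_months`, `event`).
#' Readers validate headers and report the expected columns on mismatch;
#' writers round-trip losslessly at the documented precision (probabilities
#' to 1e-12, times to 1e-6).
#'
#' @param path File path.
#' @param curve,risk,ipd Objects to serialize.
#' @param arm,endpoint Labels attached on read.
#' @name pipeline_io
NULL

check_header <- function(df, expected, path) {
  if (!all(expected %in% names(df)))
    stop("file '", path, "' must have columns: ",
         paste(expected, collapse = ", "), " (found: ",
         paste(names(df), collapse = ", "), ")")
  for (col in expected)
    if (!is.numeric(df[[col]]))
      stop("file '", path, "': column '", col, "' must be numeric")
}

#' @rdname pipeline_io
#' @export
write_curve_csv <- function(curve, path) {
  df <- data.frame(time_months = round(curve$time, 6),
                   survival = round(curve$survival, 12))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_curve_csv <- function(path, arm = "", endpoint = "") {
  df <- utils::read.csv(path)
  check_header(df, c("time_months", "survival"), path)
  digitized_curve(df$time_months, df$survival, arm = arm,
                  endpoint = endpoint, check = FALSE)
}

#' @rdname pipeline_io
#' @export
write_risk_csv <- function(risk, path) {
  utils::write.csv(data.frame(time_months = risk$time,
                              n_at_risk = risk$n_at_risk),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_risk_csv <- function(path) {
  df <- utils::read.csv(path)
  check_header(df, c("time_months", "n_at_risk"), path)
  risk_table(df$time_months, df$n_at_risk)
}

#' @rdname pipeline_io
#' @export
write_ipd_csv <- function(ipd, path) {
  utils::write.csv(data.frame(time_months = round(ipd$time, 6),
                              event = as.integer(ipd$event)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_ipd_csv <- function(path) {
  df <- utils::read.csv(path)
  check_header(df, c("time_months", "event"), path)
  data.frame(time = df$time_months, event = as.integer(df$event))
}

#' Pipeline run configuration
#'
#' @param country `"US"` or `"China"` (economic perspective).
#' @param population `"ITT"` or `"China"` (survival inputs; the China payer
#'   analysis conventionally pairs with the China subgroup).
#' @param scenario A [trial_scenario()]; defaults to
#'   `default_scenario(population)`.
#' @param n_cycles Model horizon in monthly cycles.
#' @param pfs2_exit_rate Per-month PFS2 exit hazard (see [psm_config()]).
#' @param half_cycle_correction Trapezoid accrual flag.
#' @param econ_overrides Named list of parameter-path overrides applied to
#'   [make_parameter_set()] output.
#' @param analyses Character subset of
#'   `c("base", "owsa", "twoway", "psa", "threshold", "scenarios")`.
#' @param n_psa_draws Monte Carlo draws for the PSA.
#' @param out_dir Output directory (`NULL` for no files).
#' @param seed Integer master seed for simulation and PSA.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(country = "US", population = NULL,
                            scenario = NULL, n_cycles = 240L,
                            pfs2_exit_rate = log(2) / 6,
                            half_cycle_correction = FALSE,
                            econ_overrides = NULL,
                            analyses = "base", n_psa_draws = 1000L,
                            out_dir = NULL, seed = 1L) {
  if (is.null(population)) population <- if (country == "China") "China" else "ITT"
  ok <- c("base", "owsa", "twoway", "psa", "threshold", "scenarios")
  if (!all(analyses %in% ok))
    stop("unknown analysis toggle: ", paste(setdiff(analyses, ok), collapse = ", "))
  if (is.null(scenario)) scenario <- default_scenario(population, seed = seed)
  structure(list(country = country, population = population,
                 scenario = scenario, n_cycles = as.integer(n_cycles),
                 pfs2_exit_rate = pfs2_exit_rate,
                 half_cycle_correction = isTRUE(half_cycle_correction),
                 econ_overrides = econ_overrides, analyses = analyses,
                 n_psa_draws = as.integer(n_psa_draws),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [pipeline_config()] arguments (scalar fields
#' plus an `econ_overrides` mapping of dotted parameter paths to values).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  bad <- setdiff(names(y), names(formals(pipeline_config)))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, args)
}

# apply named path -> value overrides to an econ_params list
apply_overrides <- function(params, overrides) {
  for (nm in names(overrides)) params <- param_set(params, nm, overrides[[nm]])
  params
}

arm_schedules <- function(params) {
  list(intervention = schedule_nivo_ipi(),
       comparator = schedule_comparator(params$len_prop,
                                        params$prop_weight_ge60))
}

# fit + model-average one arm/endpoint; returns ensemble, grids and report
fit_endpoint <- function(ipd, n_cycles, curve = NULL) {
  fits <- fit_all_families(ipd)
  ens <- akaike_weights(fits)
  grid <- survivor_grid(ens, n_cycles)
  gof <- if (!is.null(curve)) goodness_of_fit_report(ens, curve) else NULL
  list(ensemble = ens, grid = grid, gof = gof)
}

#' Run the full cost-effectiveness pipeline
#'
#' Executes the end-to-end chain on a synthetic trial: simulate IPD from
#' the scenario's ground truth, derive the published-style curve and risk
#' table per arm and endpoint, reconstruct pseudo-IPD from those artifacts,
#' fit the five parametric families and model-average them, build the
#' four-state partitioned survival traces, accrue discounted costs and
#' QALYs under the country parameter set, and compute the incremental
#' results; requested uncertainty analyses run on top. With `out_dir` set,
#' all tables are written as CSV along with a JSON manifest (config hash,
#' seed, package version). Identical config and seed give identical output.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a `pipeline_result` bundle: inputs, reconstructed
#'   data, ensembles, traces, strategy results, `ce`, and any analysis
#'   tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  scen <- config$scenario
  params <- apply_overrides(make_parameter_set(config$country),
                            config$econ_overrides)
  psm <- psm_config(config$n_cycles, config$pfs2_exit_rate,
                    config$half_cycle_correction)

  ipd_true <- simulate_ipd(scen, seed = config$seed)
  arms <- scen$arm_names
  roles <- c(intervention = arms[1], comparator = arms[2])

  published <- list(); recon <- list(); fits <- list()
  for (role in names(roles)) {
    for (ep in c("os", "pfs")) {
      sub <- ipd_true[ipd_true$arm == roles[[role]] &
                        ipd_true$endpoint == ep, ]
      pub <- km_from_ipd(sub, scen$risk_table_interval,
                         arm = roles[[role]], endpoint = ep)
      rec <- reconstruct_ipd(pub$curve, pub$risk)
      key <- paste(role, ep, sep = ".")
      published[[key]] <- pub
      recon[[key]] <- rec
      fits[[key]] <- fit_endpoint(rec, config$n_cycles, pub$curve)
    }
  }

  traces <- list(
    intervention = compute_occupancy(fits[["intervention.pfs"]]$grid,
                                     fits[["intervention.os"]]$grid, psm),
    comparator = compute_occupancy(fits[["comparator.pfs"]]$grid,
                                   fits[["comparator.os"]]$grid, psm))

  sched <- arm_schedules(params)
  strategies <- list(
    intervention = accumulate(traces$intervention, params,
                              sched$intervention, "intervention",
                              label = roles[["intervention"]],
                              half_cycle_correction = psm$half_cycle_correction),
    comparator = accumulate(traces$comparator, params, sched$comparator,
                            "comparator", label = roles[["comparator"]],
                            half_cycle_correction = psm$half_cycle_correction))
  ce <- icer(strategies$intervention, strategies$comparator, params$wtp)

  bundle <- structure(
    list(config = config, params = params, psm = psm, ipd = ipd_true,
         published = published, recon = recon, fits = fits, traces = traces,
         strategies = strategies, ce = ce,
         base_table = results_table(strategies$intervention,
                                    strategies$comparator, ce)),
    class = "pipeline_result")

  model_fn <- build_model_fn(bundle)
  if ("owsa" %in% config$analyses)
    bundle$owsa <- one_way_sa(model_fn, default_owsa_ranges(params))
  if ("twoway" %in% config$analyses) {
    base_n <- params$prices$nivolumab; base_i <- params$prices$ipilimumab
    bundle$twoway <- two_way_sa(model_fn, "prices.nivolumab",
                                seq(0.5, 1.5, length.out = 5) * base_n,
                                "prices.ipilimumab",
                                seq(0.5, 1.5, length.out = 5) * base_i,
                                params$wtp)
  }
  if ("psa" %in% config$analyses) {
    spec <- default_psa_spec(params, n_draws = config$n_psa_draws,
                             seed = config$seed + 1L)
    bundle$psa_draws <- psa(model_fn, spec)
    wtp_grid <- if (config$country == "US") c(50000, 100000, 150000)
                else c(22031.53, 39933.67, 95160.78)
    bundle$ceac <- ceac(bundle$psa_draws, wtp_grid)
  }
  if ("threshold" %in% config$analyses)
    bundle$threshold <- list(
      nivolumab = price_threshold(model_fn, "prices.nivolumab",
                                  params$prices$nivolumab, params$wtp),
      ipilimumab = price_threshold(model_fn, "prices.ipilimumab",
                                   params$prices$ipilimumab, params$wtp),
      both = price_threshold(model_fn,
                             c("prices.nivolumab", "prices.ipilimumab"),
                             c(params$prices$nivolumab,
                               params$prices$ipilimumab), params$wtp))
  if ("scenarios" %in% config$analyses)
    bundle$scenarios <- do.call(rbind, lapply(
      list(list(horizon_years = 4), list(horizon_years = 5),
           list(horizon_years = 10), list(exclude_ae_disutility = TRUE),
           list(pfs_only_accrual = TRUE), list(comparator = "lenvatinib"),
           list(comparator = "sorafenib")),
      function(s) do.call(run_scenario, c(list(bundle), s))))

  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  invisible(bundle)
}

#' Deterministic re-evaluation closure over a pipeline result
#'
#' Returns `function(overrides)` that applies named parameter-path
#' overrides to the bundle's economic parameters, re-accrues both arms on
#' the fixed survival traces, and returns the [icer()] result. Survival is
#' held at base: parameter uncertainty propagates through costs, utilities
#' and discounting only.
#'
#' @param bundle A [run_pipeline()] result.
#' @return A function suitable for [one_way_sa()], [psa()],
#'   [price_threshold()].
#' @export
build_model_fn <- function(bundle) {
  force(bundle)
  function(overrides = NULL) {
    p <- apply_overrides(bundle$params, overrides)
    sched <- arm_schedules(p)
    int <- accumulate(bundle$traces$intervention, p, sched$intervention,
                      "intervention",
                      half_cycle_correction = bundle$psm$half_cycle_correction)
    comp <- accumulate(bundle$traces$comparator, p, sched$comparator,
                       "comparator",
                       half_cycle_correction = bundle$psm$half_cycle_correction)
    icer(int, comp, p$wtp)
  }
}

#' Default one-way sensitivity ranges
#'
#' Plus/minus 20% around base for the main scalar cost, price, weight and
#' utility parameters (utilities capped at 1), with the discount rate
#' varied over 0 to 8% annually.
#'
#' @param params An economic parameter set.
#' @return Data frame for [one_way_sa()].
#' @export
default_owsa_ranges <- function(params) {
  paths <- c("prices.nivolumab", "prices.ipilimumab", "prices.lenvatinib",
             "prices.sorafenib", "admin_cost_per_infusion",
             "followup_cost_per_cycle", "bsc_cost_per_cycle", "eol_cost",
             "weight_kg", "prop_male", "len_prop",
             "utilities.pfs", "utilities.pfs2", "utilities.pd")
  base <- vapply(paths, function(p) param_get(params, p), numeric(1))
  lo <- base * 0.8
  hi <- base * 1.2
  cap <- grepl("^utilities|^len_prop|^prop_male", paths)
  hi[cap] <- pmin(hi[cap], 1)
  out <- data.frame(param = paths, base = base, low = lo, high = hi,
                    row.names = NULL)
  rbind(out, data.frame(param = "discount_rate",
                        base = params$discount_rate, low = 0, high = 0.08))
}

#' Default probabilistic sensitivity specification
#'
#' Gamma draws (method of moments) for every cost parameter and beta draws
#' for the three alive-state utilities, each with SD equal to 20% of the
#' base value.
#'
#' @param params An economic parameter set.
#' @param n_draws,seed Passed to [psa_spec()].
#' @return A [psa_spec()].
#' @export
default_psa_spec <- function(params, n_draws = 1000L, seed = 1L) {
  cost_paths <- c("prices.nivolumab", "prices.ipilimumab",
                  "prices.lenvatinib", "prices.sorafenib",
                  "admin_cost_per_infusion", "followup_cost_per_cycle",
                  "bsc_cost_per_cycle", "eol_cost")
  util_paths <- c("utilities.pfs", "utilities.pfs2", "utilities.pd")
  paths <- c(cost_paths, util_paths)
  base <- vapply(paths, function(p) param_get(params, p), numeric(1))
  psa_spec(data.frame(param = paths, base = base,
                      dist = c(rep("gamma", length(cost_paths)),
                               rep("beta", length(util_paths))),
                      sd = 0.2 * base, row.names = NULL),
           n_draws = n_draws, seed = seed)
}

#' Scenario analysis on a fitted pipeline bundle
#'
#' Re-runs the decision model under a modified assumption and returns one
#' results row. Supported keys: `horizon_years` (4, 5, 10 or 20),
#' `exclude_ae_disutility`, `pfs_only_accrual` (costs and QALYs accrue in
#' the PFS state only), `comparator` (`"blend"`, `"lenvatinib"`,
#' `"sorafenib"`), and `pfs_source` (a list with `intervention` and
#' `comparator` survivor grids replacing the fitted PFS curves, e.g.
#' investigator-assessed curves).
#'
#' @param bundle A [run_pipeline()] result.
#' @param horizon_years Model horizon in years.
#' @param exclude_ae_disutility Zero out adverse-event disutilities.
#' @param pfs_only_accrual Restrict accrual to the PFS state.
#' @param comparator Comparator drug mix.
#' @param pfs_source Alternative PFS survivor grids (see above).
#' @return One-row data frame: scenario label, per-arm costs and QALYs,
#'   increments, ICER.
#' @export
run_scenario <- function(bundle, horizon_years = NULL,
                         exclude_ae_disutility = FALSE,
                         pfs_only_accrual = FALSE,
                         comparator = c("blend", "lenvatinib", "sorafenib"),
                         pfs_source = NULL) {
  comparator <- match.arg(comparator)
  p <- bundle$params
  label <- character(0)

  n_cycles <- bundle$psm$n_cycles
  if (!is.null(horizon_years)) {
    if (!horizon_years %in% c(4, 5, 10, 20))
      stop("horizon_years must be one of 4, 5, 10, 20")
    n_cycles <- as.integer(horizon_years * 12)
    label <- c(label, paste0("horizon_", horizon_years, "y"))
  }
  psm <- psm_config(n_cycles, bundle$psm$pfs2_exit_rate,
                    bundle$psm$half_cycle_correction)
  grids <- list(
    intervention = list(pfs = bundle$fits[["intervention.pfs"]]$grid,
                        os = bundle$fits[["intervention.os"]]$grid),
    comparator = list(pfs = bundle$fits[["comparator.pfs"]]$grid,
                      os = bundle$fits[["comparator.os"]]$grid))
  if (!is.null(pfs_source)) {
    grids$intervention$pfs <- pfs_source$intervention
    grids$comparator$pfs <- pfs_source$comparator
    label <- c(label, "alternative_pfs")
  }
  traces <- lapply(grids, function(g) compute_occupancy(g$pfs, g$os, psm))

  if (exclude_ae_disutility) {
    p$ae$intervention$disutility <- 0 * p$ae$intervention$disutility
    p$ae$comparator$disutility <- 0 * p$ae$comparator$disutility
    label <- c(label, "exclude_ae_disutility")
  }
  if (pfs_only_accrual) label <- c(label, "pfs_only")
  if (comparator != "blend") {
    p$len_prop <- if (comparator == "lenvatinib") 1 else 0
    label <- c(label, paste0("comparator_", comparator))
  }
  if (!length(label)) label <- "base"

  sched <- arm_schedules(p)
  int <- accumulate(traces$intervention, p, sched$intervention,
                    "intervention",
                    half_cycle_correction = psm$half_cycle_correction,
                    pfs_only = pfs_only_accrual)
  comp <- accumulate(traces$comparator, p, sched$comparator, "comparator",
                     half_cycle_correction = psm$half_cycle_correction,
                     pfs_only = pfs_only_accrual)
  ce <- icer(int, comp, p$wtp)
  data.frame(scenario = paste(label, collapse = "+"),
             cost_intervention = int$cost, cost_comparator = comp$cost,
             qaly_intervention = int$qaly, qaly_comparator = comp$qaly,
             dcost = ce$dcost, dqaly = ce$deffect, icer = ce$icer)
}

money <- function(x) sprintf("%.2f", x)

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, paste0(...))
  for (key in names(bundle$published)) {
    write_curve_csv(bundle$published[[key]]$curve, fp("curve_", key, ".csv"))
    write_risk_csv(bundle$published[[key]]$risk, fp("risk_", key, ".csv"))
    write_ipd_csv(bundle$recon[[key]], fp("ipd_", key, ".csv"))
    gof <- bundle$fits[[key]]$gof
    tab <- gof$table
    utils::write.csv(tab, fp("fits_", key, ".csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(cycle = bundle$fits[[key]]$grid$cycle,
                 S = round(bundle$fits[[key]]$grid$S, 12)),
      fp("survivor_", key, ".csv"), row.names = FALSE)
  }
  for (role in names(bundle$traces)) {
    tr <- bundle$traces[[role]]
    tr[-1] <- lapply(tr[-1], function(col) round(col, 12))
    utils::write.csv(tr, fp("trace_", role, ".csv"), row.names = FALSE)
  }
  bt <- bundle$base_table
  for (col in c("cost", "incremental_cost", "icer"))
    bt[[col]] <- money(bt[[col]])
  utils::write.csv(bt, fp("base_case.csv"), row.names = FALSE)
  if (!is.null(bundle$owsa))
    utils::write.csv(bundle$owsa, fp("owsa.csv"), row.names = FALSE)
  if (!is.null(bundle$twoway))
    utils::write.csv(bundle$twoway, fp("twoway.csv"), row.names = FALSE)
  if (!is.null(bundle$psa_draws))
    utils::write.csv(bundle$psa_draws, fp("psa_draws.csv"), row.names = FALSE)
  if (!is.null(bundle$ceac))
    utils::write.csv(bundle$ceac, fp("ceac.csv"), row.names = FALSE)
  if (!is.null(bundle$threshold))
    jsonlite::write_json(bundle$threshold, fp("threshold.json"),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$scenarios))
    utils::write.csv(bundle$scenarios, fp("scenarios.csv"), row.names = FALSE)
  jsonlite::write_json(manifest(bundle), fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

manifest <- function(bundle) {
  cfg <- bundle$config
  cfg$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg, tmp, version = 2)
  list(config_hash = unname(tools::md5sum(tmp)),
       seed = bundle$config$seed,
       country = bundle$config$country,
       population = bundle$config$population,
       package_version = as.character(utils::packageVersion("psmcea")),
       r_version = paste(R.version$major, R.version$minor, sep = "."))
}
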