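# shared fixtures built in code

# single-family, single-arm scenario for targeted simulation tests
one_arm_scenario <- function(family, params, n, admin_censor_time = 1e6,
                             accrual_window = 0, correlate = FALSE,
                             seed = 1L) {
  truth <- list(
    A = list(pfs = list(family = family, params = params),
             os = list(family = family, params = params)),
    B = list(pfs = list(family = "exponential", params = c(rate = 0.1)),
             os = list(family = "exponential", params = c(rate = 0.1))))
  trial_scenario(c("A", "B"), c(n, 1L), truth, correlate = correlate,
                 admin_censor_time = admin_censor_time,
                 accrual_window = accrual_window, seed = seed)
}

sim_one_arm <- function(family, params, n, seed = 1L, ...) {
  sc <- one_arm_scenario(family, params, n, seed = seed, ...)
  ipd <- simulate_ipd(sc, seed = seed)
  ipd[ipd$arm == "A" & ipd$endpoint == "os", c("time", "event")]
}

# censored sample from one family: events before `cutoff`, censored at it
censored_sample <- function(family, params, n, cutoff, seed) {
  set.seed(seed)
  t_true <- psmcea:::rfamily(family, params, n)
  data.frame(time = pmin(t_true, cutoff),
             event = as.integer(t_true <= cutoff))
}

# hand-built ensemble from explicit models (bypasses fitting)
manual_model <- function(family, params, loglik = -100, n = 100) {
  k <- if (family == "exponential") 1L else 2L
  psmcea:::new_parametric_model(family, params, loglik, n, k, TRUE)
}

# exponential survivor grid over cycles 0..n
exp_grid <- function(rate, n_cycles) exp(-rate * (0:n_cycles))

# flat-cost economic parameters for accrual identity tests
simple_params <- function(discount_rate = 0, utility = 0.84,
                          followup = 0, bsc = 0, eol = 0) {
  p <- make_parameter_set("US")
  p$discount_rate <- discount_rate
  p$utilities <- list(pfs = utility, pfs2 = utility, pd = utility, death = 0)
  p$prices <- list(nivolumab = 0, ipilimumab = 0, lenvatinib = 0,
                   sorafenib = 0)
  p$admin_cost_per_infusion <- 0
  p$followup_cost_per_cycle <- followup
  p$bsc_cost_per_cycle <- bsc
  p$eol_cost <- eol
  p$subsequent$intervention <- list(proportions = numeric(0),
                                    monthly_costs = numeric(0))
  p$ae$intervention$incidence <- 0 * p$ae$intervention$incidence
  p$ae$intervention$cost <- 0 * p$ae$intervention$cost
  p$ae$intervention$disutility <- 0 * p$ae$intervention$disutility
  p
}

# state trace with every subject alive in PFS for n cycles, then dead
alive_then_dead_trace <- function(n_alive, n_total = n_alive) {
  s <- c(rep(1, n_alive + 1), rep(0, n_total - n_alive))
  compute_occupancy(s, s, psm_config(n_cycles = n_total))
}

reference_results <- function() {
  utils::read.csv(system.file("extdata", "reference_results.csv",
                              package = "psmcea"))
}

# compact pipeline bundle reused across pipeline/uncertainty tests
small_bundle <- function(seed = 5L, analyses = "base") {
  sc <- default_scenario("ITT", seed = seed)
  sc$n_per_arm <- c(120L, 120L)
  cfg <- pipeline_config(country = "US", scenario = sc, n_cycles = 240L,
                         analyses = analyses, n_psa_draws = 50L, seed = seed)
  run_pipeline(cfg)
}

.fixtures <- new.env(parent = emptyenv())
get_small_bundle <- function() {
  if (is.null(.fixtures$bundle)) .fixtures$bundle <- small_bundle()
  .fixtures$bundle
}
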