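test_that("discount factors follow the annual-rate monthly convention", {
  expect_equal(discount_factor(0, 7), 1)
  expect_equal(discount_factor(0.03, 12), 1 / 1.03)
  expect_equal(discount_factor(0.05, 24), 1 / 1.05^2)
  expect_equal(discount_factor(0.03, 0), 1)
  expect_error(discount_factor(-0.01, 1), ">= 0")
})

test_that("oral and infusion dosing arithmetic matches the regimen rules", {
  # sorafenib 400 mg twice daily over a 365.25/12-day cycle
  sor <- drug_schedule(drug_component("sorafenib", "daily", 800,
                                      route = "oral"))
  expect_equal(drug_cost_per_cycle(sor, 70, list(sorafenib = 1), 1),
               800 * 365.25 / 12)
  expect_equal(drug_cost_per_cycle(sor, 70, list(sorafenib = 1), 1), 24350)

  # nivolumab induction 1 mg/kg q3w at 70 kg: dose cost 70p per administration
  nivo <- drug_schedule(drug_component("nivolumab", "per_kg", 1,
                                       interval_days = 21, max_doses = 4))
  p <- 25
  # cycle 1 covers days [0, 30.4): administrations on days 0 and 21
  expect_equal(drug_cost_per_cycle(nivo, 70, list(nivolumab = p), 1),
               2 * 70 * p)
  expect_equal(psmcea:::infusions_per_cycle(nivo, 1), 2)

  # induction cap: four combined doses end on day 63; later cycles have none
  ipi <- drug_schedule(drug_component("ipilimumab", "per_kg", 3,
                                      interval_days = 21, max_doses = 4))
  total_ipi <- sum(vapply(1:12, function(i)
    drug_cost_per_cycle(ipi, 70, list(ipilimumab = 1), i), numeric(1)))
  expect_equal(total_ipi, 4 * 3 * 70)
  expect_equal(drug_cost_per_cycle(ipi, 70, list(ipilimumab = 1), 4), 0)

  # maintenance 480 mg flat applies after the induction block
  full <- schedule_nivo_ipi()
  c4 <- drug_cost_per_cycle(full, 70, list(nivolumab = 1, ipilimumab = 1), 4)
  expect_equal(c4, 480)

  expect_error(drug_cost_per_cycle(full, 70, list(nivolumab = 1), 1),
               "no price")
  expect_error(drug_cost_per_cycle(full, 0, list(nivolumab = 1), 1), "> 0")

  # vial wastage rounds each administration up to whole vials
  vial <- drug_schedule(drug_component("ipilimumab", "per_kg", 3,
                                       interval_days = 1e9,
                                       vial_size_mg = 50))
  expect_equal(drug_cost_per_cycle(vial, 65, list(ipilimumab = 1), 1), 200)

  # duration caps limit oral exposure within a cycle
  capped <- drug_schedule(drug_component("sorafenib", "daily", 800,
                                         route = "oral", max_days = 10))
  expect_equal(drug_cost_per_cycle(capped, 70, list(sorafenib = 1), 1), 8000)
  expect_equal(drug_cost_per_cycle(capped, 70, list(sorafenib = 1), 2), 0)
})

test_that("subsequent-therapy cost is a BSC-completed weighted mean", {
  expect_equal(weighted_subsequent_cost(c(0.5, 0.5), c(1000, 3000)), 2000)
  expect_equal(weighted_subsequent_cost(0.6, 2000, bsc_monthly = 500), 1400)
  expect_equal(weighted_subsequent_cost(numeric(0), numeric(0),
                                        bsc_monthly = 500), 500)
  expect_error(weighted_subsequent_cost(-0.1, 100), ">= 0")
  expect_error(weighted_subsequent_cost(c(0.7, 0.5), c(1, 1)), "sum")
})

test_that("QALY accrual reproduces the undiscounted identity and discount monotonicity", {
  tr <- alive_then_dead_trace(12, 24)
  sched <- drug_schedule(drug_component("nivolumab", "flat", 1,
                                        interval_days = 1e9))
  p0 <- simple_params(discount_rate = 0, utility = 0.84)
  res <- accumulate(tr, p0, sched, "intervention")
  expect_equal(res$qaly, 0.84)
  expect_equal(res$ly, 1)

  p3 <- simple_params(discount_rate = 0.03, utility = 0.84)
  expect_lt(accumulate(tr, p3, sched, "intervention")$qaly, res$qaly)
})

test_that("cost categories add to the total and map to the intended states", {
  tr <- alive_then_dead_trace(12, 24)
  p <- simple_params(discount_rate = 0, utility = 0.84, followup = 100,
                     bsc = 50, eol = 10000)
  sched <- drug_schedule(drug_component("nivolumab", "flat", 10,
                                        interval_days = 365.25 / 12))
  p$prices$nivolumab <- 2
  p$admin_cost_per_infusion <- 30
  res <- accumulate(tr, p, sched, "intervention")
  expect_equal(sum(res$breakdown), res$cost, tolerance = 1e-9)
  expect_equal(unname(res$breakdown["followup"]), 12 * 100)
  expect_equal(unname(res$breakdown["eol"]), 10000)  # everyone dies once
  expect_equal(unname(res$breakdown["drug"]), 12 * 10 * 2)
  expect_equal(unname(res$breakdown["administration"]), 12 * 30)
  expect_equal(unname(res$breakdown["bsc"]), 0)  # nobody reaches PD

  # an immediately-dead cohort accrues only first-cycle AE and end-of-life
  dead <- alive_then_dead_trace(0, 12)
  pae <- simple_params(discount_rate = 0, eol = 7000)
  pae$ae$intervention <- data.frame(name = "x", incidence = 0.5, cost = 1000,
                                    disutility = 0.1)
  res_dead <- accumulate(dead, pae, sched, "intervention")
  expect_equal(unname(res_dead$breakdown["ae"]), 500)
  expect_equal(unname(res_dead$breakdown["eol"]), 7000)
  expect_equal(res_dead$cost, 7500)
  expect_equal(res_dead$ly, 0)
  # AE disutility is a one-time first-cycle decrement
  expect_equal(res_dead$qaly, -0.5 * 0.1 / 12)
})

test_that("raising the PD utility toward the PFS2 value never lowers QALYs", {
  n <- 120
  tr <- compute_occupancy(exp_grid(0.08, n), exp_grid(0.03, n),
                          psm_config(n, pfs2_exit_rate = 0.2))
  p <- make_parameter_set("US")
  sched <- schedule_nivo_ipi()
  base <- accumulate(tr, p, sched, "intervention")
  p2 <- param_set(p, "utilities.pd", p$utilities$pfs2)
  expect_gte(accumulate(tr, p2, sched, "intervention")$qaly, base$qaly)
})

test_that("total discounted cost is non-increasing in the discount rate", {
  n <- 120
  tr <- compute_occupancy(exp_grid(0.08, n), exp_grid(0.03, n),
                          psm_config(n))
  p <- make_parameter_set("US")
  sched <- schedule_nivo_ipi()
  costs <- vapply(c(0, 0.03, 0.08), function(r) {
    accumulate(tr, param_set(p, "discount_rate", r), sched,
               "intervention")$cost
  }, numeric(1))
  expect_true(all(diff(costs) < 0))
})
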