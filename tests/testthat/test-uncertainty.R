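# deterministic toy decision model over a flat parameter list:
# intervention cost = units * x + shared s; comparator cost = shared s;
# QALY gain fixed at de -> ICER = units * x / de, linear in x
toy_model <- function(units = 10, de = 0.5,
                      base = list(x = 100, s = 50, y = 40, wtp = 3000)) {
  function(overrides = NULL) {
    p <- base
    for (nm in names(overrides)) p <- param_set(p, nm, overrides[[nm]])
    int <- list(cost = units * p$x + 2 * p$y + p$s, qaly = 1 + de)
    comp <- list(cost = p$s, qaly = 1)
    icer(int, comp, p$wtp)
  }
}

test_that("parameter paths address nested and tabular leaves", {
  p <- make_parameter_set("US")
  expect_equal(param_get(p, "prices.nivolumab"), 31.8)
  expect_equal(param_get(p, "utilities.pfs"), 0.84)
  expect_equal(param_get(p, "ae.intervention.incidence.2"),
               p$ae$intervention$incidence[2])
  p2 <- param_set(p, "prices.nivolumab", 10)
  expect_equal(param_get(p2, "prices.nivolumab"), 10)
  p3 <- param_set(p, "ae.comparator.cost.1", 999)
  expect_equal(p3$ae$comparator$cost[1], 999)
  expect_error(param_get(p, "prices.pembrolizumab"), "unknown parameter path")
  expect_error(param_set(p, "nope.x", 1), "unknown parameter path")
})

test_that("moment matching recovers gamma and beta hyperparameters", {
  expect_equal(gamma_from_moments(100, 20),
               c(shape = 25, scale = 4))
  b <- beta_from_moments(0.84, 0.05)
  expect_equal(unname(b["alpha"]), 44.3184, tolerance = 1e-4)
  expect_equal(unname(b["beta"]), 8.4416, tolerance = 1e-4)
  # round trip through the distribution moments
  expect_equal(unname(b["alpha"] / sum(b)), 0.84)
  expect_error(beta_from_moments(0.5, 0.5), "infeasible")
  expect_error(beta_from_moments(1.2, 0.1), "in \\(0, 1\\)")
  expect_error(gamma_from_moments(-1, 1), "> 0")
})

test_that("tornado rows rank by spread, zero out symmetric parameters, and flag failures", {
  fn <- toy_model()
  ranges <- data.frame(param = c("x", "s", "y"),
                       base = c(100, 50, 40),
                       low = c(80, 40, 32),
                       high = c(120, 60, 48))
  tor <- one_way_sa(fn, ranges)
  expect_equal(tor$param[1], "x")                 # largest lever first
  expect_equal(tor$spread[tor$param == "s"], 0)   # enters both arms equally
  base_icer <- fn()$icer
  expect_equal(tor$icer_low[tor$param == "s"], base_icer)
  # intervention-only cost parameter moves the ICER monotonically
  expect_lt(tor$icer_low[tor$param == "x"], tor$icer_high[tor$param == "x"])

  failing <- function(overrides) {
    if (!is.null(overrides$x) && overrides$x > 110) stop("boom")
    fn(overrides)
  }
  tor2 <- one_way_sa(failing, ranges)
  expect_true(tor2$failed[tor2$param == "x"])
  expect_false(any(tor2$failed[tor2$param != "x"]))
  expect_error(one_way_sa(fn, transform(ranges, low = base + 1)), "low <= base")
})

test_that("two-way grids contain the base case and are corner-monotone", {
  fn <- toy_model()
  gridA <- c(80, 100, 120)
  gridB <- c(32, 40, 48)
  tw <- two_way_sa(fn, "x", gridA, "y", gridB, wtp = 3000)
  expect_equal(nrow(tw), 9L)
  base_cell <- tw[tw$valueA == 100 & tw$valueB == 40, ]
  expect_equal(base_cell$icer, fn()$icer)
  expect_lte(tw$icer[tw$valueA == 80 & tw$valueB == 32],
             tw$icer[tw$valueA == 120 & tw$valueB == 48])
  expect_error(two_way_sa(fn, "x", 1, "y", gridB, 3000), "at least 2")
})

test_that("degenerate PSA reproduces the base case and fixed seeds reproduce draws", {
  fn <- toy_model()
  spec0 <- psa_spec(data.frame(param = c("x", "y"), base = c(100, 40),
                               dist = "gamma", sd = 0), n_draws = 20,
                    seed = 3)
  draws0 <- psa(fn, spec0)
  expect_true(all(draws0$dcost == fn()$dcost))
  expect_true(all(draws0$dqaly == fn()$deffect))

  spec1 <- psa_spec(data.frame(param = c("x", "y"), base = c(100, 40),
                               dist = "gamma"), n_draws = 50, seed = 7)
  expect_equal(spec1$params$sd, c(20, 8))        # 20% default dispersion
  d1 <- psa(fn, spec1)
  d2 <- psa(fn, spec1)
  expect_identical(d1, d2)
  d3 <- psa(fn, psa_spec(spec1$params, n_draws = 50, seed = 8))
  expect_false(identical(d1, d3))
  expect_gt(stats::sd(d1$dcost), 0)
})

test_that("acceptability probabilities are exact empirical NMB fractions", {
  single <- data.frame(draw = 1:5, dcost = 86403.43, dqaly = 0.68)
  cc <- ceac(single, c(100000, 150000))
  expect_equal(cc$probability, c(0, 1))

  mixed <- data.frame(draw = 1:4, dcost = c(-5, 10, 20, 30),
                      dqaly = c(0.1, 0.2, -0.1, 0.4))
  expect_equal(ceac(mixed, 0)$probability, 0.25)  # only the cost-saving draw
  # WTP -> infinity: every positive-gain draw counts
  expect_equal(ceac(mixed, 1e12)$probability, 0.75)
})

test_that("price-threshold bisection solves the linear toy model analytically", {
  units <- 10; de <- 0.5; wtp <- 3000
  base <- list(x = 100, s = 50, y = 0.0001, wtp = wtp)
  fn <- toy_model(units, de, base)
  # ICER(m) = (units * x * m + 2y) / de = wtp at m*
  m_star <- (wtp * de - 2 * base$y) / (units * base$x)
  sol <- price_threshold(fn, "x", base$x, wtp, bounds = c(0.01, 3))
  expect_equal(sol$status, "solved")
  expect_lt(abs(sol$achieved_icer - wtp) / wtp, 1e-4)
  expect_equal(sol$multiplier, m_star, tolerance = 1e-3)

  # WTP above the base ICER pushes the admissible multiplier above 1
  expect_gt(price_threshold(fn, "x", base$x, 2500)$multiplier,
            price_threshold(fn, "x", base$x, 1800)$multiplier)
  expect_gt(price_threshold(fn, "x", base$x, 2500)$multiplier, 1)

  # out-of-range thresholds are classified, not solved
  expect_equal(price_threshold(fn, "x", base$x, 1e7)$status, "always")
  expect_equal(price_threshold(fn, "x", base$x, 1)$status, "never")
})

test_that("joint price cuts need smaller reductions than single-drug cuts", {
  fn <- toy_model(10, 0.5, base = list(x = 60, s = 50, y = 200, wtp = 2000))
  wtp <- 1500
  single_x <- price_threshold(fn, "x", 60, wtp)
  single_y <- price_threshold(fn, "y", 200, wtp)
  joint <- price_threshold(fn, c("x", "y"), c(60, 200), wtp)
  expect_equal(single_x$status, "solved")
  expect_equal(single_y$status, "solved")
  expect_equal(joint$status, "solved")
  # the joint reduction (1 - m) is smaller than either single-drug reduction
  expect_lte(1 - joint$multiplier, 1 - single_x$multiplier + 1e-6)
  expect_lte(1 - joint$multiplier, 1 - single_y$multiplier + 1e-6)
})
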