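test_that("survivor parameterizations match their closed forms", {
  expect_equal(survival_function("exponential", c(rate = log(2) / 12), 12), 0.5)
  expect_equal(survival_function("weibull", c(shape = 2.7, scale = 9), 9),
               exp(-1))
  expect_equal(survival_function("loglogistic", c(shape = 1, scale = 10), 10),
               0.5)
  expect_equal(survival_function("lognormal",
                                 c(meanlog = log(8), sdlog = 0.5), 8), 0.5)
  # gompertz closed form and exponential limit
  expect_equal(survival_function("gompertz", c(shape = 0.1, rate = 0.05), 10),
               exp(-(0.05 / 0.1) * (exp(0.1 * 10) - 1)))
  expect_equal(survival_function("gompertz", c(shape = 1e-14, rate = 0.05), 10),
               exp(-0.05 * 10))

  t <- seq(0, 120, by = 0.5)
  for (fam in list(c("exponential", "rate=0.05"),
                   c("weibull", "shape=1.4;scale=20"),
                   c("gompertz", "shape=0.05;rate=0.03"),
                   c("lognormal", "meanlog=2.8;sdlog=0.9"),
                   c("loglogistic", "shape=1.8;scale=18"))) {
    kv <- strsplit(strsplit(fam[2], ";")[[1]], "=")
    params <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                              vapply(kv, `[`, "", 1))
    s <- survival_function(fam[1], params, t)
    expect_equal(s[1], 1)
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
  expect_error(survival_function("weibull", c(shape = -1, scale = 2), 1),
               "positive")
  expect_error(survival_function("exponential", c(rate = 0.1), -1), ">= 0")
})

test_that("exponential MLE equals the closed form d over total time, exactly", {
  fit <- fit_parametric(data.frame(time = c(1, 2, 3, 4),
                                   event = c(1, 1, 1, 0)), "exponential")
  expect_identical(unname(fit$params["rate"]), 3 / 10)
  expect_equal(fit$aic, 2 * 1 - 2 * fit$loglik)
  expect_equal(fit$bic, 1 * log(4) - 2 * fit$loglik)
  expect_error(fit_parametric(data.frame(time = c(1, 2), event = c(0, 0)),
                              "exponential"), "censored")
})

test_that("censored MLE recovers generating parameters for all five families", {
  cases <- list(
    list(family = "exponential", params = c(rate = 0.05), cutoff = 40),
    list(family = "weibull", params = c(shape = 1.4, scale = 20), cutoff = 35),
    list(family = "gompertz", params = c(shape = 0.04, rate = 0.015),
         cutoff = 40),
    list(family = "lognormal", params = c(meanlog = 2.9, sdlog = 0.8),
         cutoff = 45),
    list(family = "loglogistic", params = c(shape = 1.7, scale = 18),
         cutoff = 40))
  for (cs in cases) {
    dat <- censored_sample(cs$family, cs$params, 5000, cs$cutoff, seed = 101)
    cens_frac <- 1 - mean(dat$event)
    expect_gt(cens_frac, 0.10)
    expect_lt(cens_frac, 0.45)
    fit <- fit_parametric(dat, cs$family)
    expect_true(fit$converged)
    rel <- abs(fit$params[names(cs$params)] - cs$params) / abs(cs$params)
    tol <- ifelse(cs$family == "gompertz" & names(cs$params) == "shape",
                  0.10, 0.05)
    expect_true(all(rel < tol),
                info = paste(cs$family, paste(round(rel, 4), collapse = " ")))
  }
})

test_that("in-package MLE agrees with an independent fitter", {
  dat <- censored_sample("weibull", c(shape = 1.3, scale = 18), 800, 30,
                         seed = 55)
  ours <- fit_parametric(dat, "weibull")
  ref <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = dat,
                               dist = "weibull")
  expect_equal(ours$loglik, ref$loglik, tolerance = 1e-6)
  expect_equal(unname(ours$params["shape"]), unname(ref$res["shape", "est"]),
               tolerance = 1e-4)
  expect_equal(unname(ours$params["scale"]), unname(ref$res["scale", "est"]),
               tolerance = 1e-4)

  dat2 <- censored_sample("gompertz", c(shape = 0.08, rate = 0.02), 800, 40,
                          seed = 56)
  ours2 <- fit_parametric(dat2, "gompertz")
  ref2 <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = dat2,
                                dist = "gompertz")
  expect_equal(ours2$loglik, ref2$loglik, tolerance = 1e-6)
})

test_that("Akaike weights are normalized, translation-invariant and collapse under large deltas", {
  mk <- function(aic) {
    m <- manual_model("exponential", c(rate = 0.1))
    m$loglik <- (2 * m$k - aic) / 2
    m$aic <- aic
    m
  }
  equal <- akaike_weights(lapply(rep(100, 5), mk))
  expect_equal(equal$weights, rep(0.2, 5))
  expect_equal(sum(equal$weights), 1, tolerance = 1e-12)

  two <- akaike_weights(lapply(c(100, 102), mk))
  expect_equal(unname(two$weights), c(1, exp(-1)) / (1 + exp(-1)),
               tolerance = 1e-10)
  expect_equal(round(unname(two$weights), 4), c(0.7311, 0.2689))

  shifted <- akaike_weights(lapply(c(100, 102) + 57.3, mk))
  expect_equal(shifted$weights, two$weights, tolerance = 1e-12)

  far <- akaike_weights(lapply(c(100, 300), mk))
  expect_lt(far$weights[2], 1e-40)

  bad <- mk(100); bad$aic <- NaN
  expect_error(akaike_weights(list(bad, mk(101))), "non-finite")
})

test_that("model-averaged survivor matches closed forms and stays bounded", {
  e1 <- manual_model("exponential", c(rate = 0.05))
  e2 <- manual_model("exponential", c(rate = 0.10))
  ens <- akaike_weights(list(e1, e2))  # equal logliks, equal k -> 0.5/0.5
  expect_equal(unname(ens$weights), c(0.5, 0.5))
  expect_equal(bma_survival(ens, 10), 0.5 * exp(-0.5) + 0.5 * exp(-1),
               tolerance = 1e-12)
  expect_equal(bma_survival(ens, 10), 0.4872051, tolerance = 1e-6)
  expect_equal(bma_survival(ens, 0), 1)

  single <- akaike_weights(list(e1))
  t <- 0:120
  expect_equal(bma_survival(single, t),
               survival_function("exponential", c(rate = 0.05), t))

  w <- manual_model("weibull", c(shape = 1.5, scale = 25))
  mix <- akaike_weights(list(e1, w))
  s_mix <- bma_survival(mix, t)
  s_lo <- pmin(survival_function("exponential", c(rate = 0.05), t),
               survival_function("weibull", c(shape = 1.5, scale = 25), t))
  s_hi <- pmax(survival_function("exponential", c(rate = 0.05), t),
               survival_function("weibull", c(shape = 1.5, scale = 25), t))
  expect_true(all(s_mix >= s_lo - 1e-12 & s_mix <= s_hi + 1e-12))
  expect_true(all(diff(s_mix) <= 1e-12))
})

test_that("goodness-of-fit report covers every family and is exact on self-generated curves", {
  ipd <- sim_one_arm("weibull", c(shape = 1.3, scale = 20), 400, seed = 77,
                     admin_censor_time = 35, accrual_window = 6)
  fits <- fit_all_families(ipd)
  ens <- akaike_weights(fits)
  km <- km_estimate(ipd)
  rep1 <- goodness_of_fit_report(ens, km)
  expect_equal(nrow(rep1$table), 5L)
  expect_lt(rep1$sup_norm, 0.05)
  expect_equal(sum(rep1$table$weight), 1, tolerance = 1e-12)

  # a curve read off the ensemble itself deviates by exactly zero
  grid <- seq(0, 36, by = 3)
  self_curve <- digitized_curve(grid, bma_survival(ens, grid))
  rep2 <- goodness_of_fit_report(ens, self_curve)
  expect_equal(rep2$sup_norm, 0, tolerance = 1e-12)
  expect_equal(rep2$mad, 0, tolerance = 1e-12)
})
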