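#' Parametric survivor functions
#'
#' Evaluates S(t) for the five families used for extrapolation, with the
#' conventional health-technology-assessment parameterizations:
#' \describe{
#'   \item{exponential}{`S = exp(-rate * t)`}
#'   \item{weibull}{`S = exp(-(t/scale)^shape)`}
#'   \item{gompertz}{`S = exp(-(rate/shape) * (exp(shape*t) - 1))`; a shape
#'     near zero falls back to the exponential limit, a negative shape gives
#'     the defective (plateauing) form}
#'   \item{lognormal}{`S = 1 - pnorm((log t - meanlog)/sdlog)`}
#'   \item{loglogistic}{`S = 1 / (1 + (t/scale)^shape)`}
#' }
#'
#' @param family One of `"exponential"`, `"weibull"`, `"gompertz"`,
#'   `"lognormal"`, `"loglogistic"`.
#' @param params Named numeric parameters (see above).
#' @param t Times (months, >= 0); vectorized.
#' @return Survival probabilities, `S(0) = 1`, non-increasing in `t`.
#' @export
survival_function <- function(family, params, t) {
  check_family(family, params)
  if (any(t < 0)) stop("t must be >= 0")
  p <- as.list(unlist(params))
  switch(family,
    exponential = exp(-p$rate * t),
    weibull     = exp(-(t / p$scale)^p$shape),
    gompertz    = if (abs(p$shape) < 1e-10) exp(-p$rate * t)
                  else exp(-(p$rate / p$shape) * expm1(p$shape * t)),
    lognormal   = ifelse(t == 0, 1,
                         stats::pnorm((log(pmax(t, .Machine$double.xmin)) -
                                       p$meanlog) / p$sdlog,
                                      lower.tail = FALSE)),
    loglogistic = 1 / (1 + (t / p$scale)^p$shape))
}

# log density per family (t > 0), used by the censored likelihood
log_density <- function(family, params, t) {
  p <- as.list(unlist(params))
  switch(family,
    exponential = log(p$rate) - p$rate * t,
    weibull     = stats::dweibull(t, shape = p$shape, scale = p$scale,
                                  log = TRUE),
    gompertz    = {
      logS <- if (abs(p$shape) < 1e-10) -p$rate * t
              else -(p$rate / p$shape) * expm1(p$shape * t)
      log(p$rate) + p$shape * t + logS   # hazard rate*exp(shape*t) times S
    },
    lognormal   = stats::dlnorm(t, meanlog = p$meanlog, sdlog = p$sdlog,
                                log = TRUE),
    loglogistic = log(p$shape / p$scale) +
      (p$shape - 1) * log(t / p$scale) -
      2 * log1p((t / p$scale)^p$shape))
}

# log survivor, numerically stable
log_survival <- function(family, params, t) {
  p <- as.list(unlist(params))
  switch(family,
    exponential = -p$rate * t,
    weibull     = -(t / p$scale)^p$shape,
    gompertz    = if (abs(p$shape) < 1e-10) -p$rate * t
                  else -(p$rate / p$shape) * expm1(p$shape * t),
    lognormal   = stats::plnorm(t, meanlog = p$meanlog, sdlog = p$sdlog,
                                lower.tail = FALSE, log.p = TRUE),
    loglogistic = -log1p((t / p$scale)^p$shape))
}

neg_loglik <- function(family, params, time, event) {
  ll <- sum(log_density(family, params, time[event == 1])) +
    sum(log_survival(family, params, time[event == 0]))
  if (!is.finite(ll)) return(1e12)
  -ll
}

# parameter transforms: positive parameters fitted on the log scale;
# gompertz shape and lognormal meanlog stay on the natural scale
param_transform <- function(family) {
  switch(family,
    exponential = list(names = "rate", to = log, from = exp),
    weibull     = list(names = c("shape", "scale"), to = log, from = exp),
    gompertz    = list(names = c("shape", "rate"),
                       to = function(x) c(x[1], log(x[2])),
                       from = function(x) c(x[1], exp(x[2]))),
    lognormal   = list(names = c("meanlog", "sdlog"),
                       to = function(x) c(x[1], log(x[2])),
                       from = function(x) c(x[1], exp(x[2]))),
    loglogistic = list(names = c("shape", "scale"), to = log, from = exp))
}

# moment/regression-based starting values
start_values <- function(family, time, event) {
  d <- sum(event)
  rate <- if (d > 0) d / sum(time) else 1 / mean(time)
  if (family == "exponential") return(c(rate = rate))
  if (family == "gompertz") return(c(shape = 0.01, rate = rate))
  # AFT families: survreg gives consistent starts when it converges
  sr <- tryCatch({
    dist <- c(weibull = "weibull", lognormal = "lognormal",
              loglogistic = "loglogistic")[[family]]
    fit <- survival::survreg(survival::Surv(time, event) ~ 1, dist = dist)
    mu <- unname(stats::coef(fit)[1]); sc <- fit$scale
    switch(family,
      weibull     = c(shape = 1 / sc, scale = exp(mu)),
      lognormal   = c(meanlog = mu, sdlog = sc),
      loglogistic = c(shape = 1 / sc, scale = exp(mu)))
  }, error = function(e) NULL)
  if (!is.null(sr) && all(is.finite(sr))) return(sr)
  switch(family,
    weibull     = c(shape = 1, scale = 1 / rate),
    lognormal   = c(meanlog = log(stats::median(time)), sdlog = 1),
    loglogistic = c(shape = 1, scale = stats::median(time)))
}

#' Censored maximum-likelihood fit of one parametric family
#'
#' Maximizes the right-censored log-likelihood
#' `sum(log f(t_i)) + sum(log S(t_j))` over events i and censored j. The
#' exponential rate has the closed form `events / total follow-up time` and
#' is computed exactly; the other families use a derivative-free optimizer
#' (Nelder-Mead on transformed parameters, restarted from jittered starting
#' values, convergence tolerance 1e-8 on the log-likelihood).
#'
#' @param ipd Data frame with columns `time` (> 0) and `event` (1/0).
#' @param family Family name (see [survival_function()]).
#' @param n_restarts Number of jittered restarts after the primary start.
#' @return A `parametric_model`: list with `family`, `params`, `loglik`,
#'   `aic`, `bic`, `n`, `k`, `converged`.
#' @export
fit_parametric <- function(ipd, family, n_restarts = 3L) {
  time <- ipd$time
  event <- ipd$event
  if (any(time <= 0)) stop("times must be positive")
  d <- sum(event)
  n <- length(time)
  k <- if (family == "exponential") 1L else 2L
  if (family == "exponential" && d == 0)
    stop("all observations censored: exponential MLE is the boundary rate 0")
  if (k >= 2L && d < 2L)
    stop("family '", family, "' needs at least 2 events")

  if (family == "exponential") {
    rate <- d / sum(time)
    ll <- -neg_loglik("exponential", c(rate = rate), time, event)
    return(new_parametric_model(family, c(rate = rate), ll, n, k, TRUE))
  }

  tr <- param_transform(family)
  start <- start_values(family, time, event)
  obj <- function(theta) {
    par <- stats::setNames(tr$from(theta), tr$names)
    neg_loglik(family, par, time, event)
  }
  starts <- list(tr$to(unname(start)))
  jit <- list(c(0.3, -0.3), c(-0.3, 0.3), c(0.5, 0.5))  # deterministic restarts
  for (j in seq_len(min(n_restarts, length(jit))))
    starts[[j + 1]] <- starts[[1]] + jit[[j]]
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-8) best <- fit
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e12)
    stop("fit_parametric did not converge for family '", family, "'")
  params <- stats::setNames(tr$from(best$par), tr$names)
  new_parametric_model(family, params, -best$value, n, k,
                       best$convergence == 0)
}

new_parametric_model <- function(family, params, loglik, n, k, converged) {
  structure(list(family = family, params = params, loglik = loglik,
                 aic = 2 * k - 2 * loglik, bic = k * log(n) - 2 * loglik,
                 n = n, k = k, converged = converged),
            class = "parametric_model")
}

#' @export
print.parametric_model <- function(x, ...) {
  cat("<parametric_model>", x$family, "|",
      paste(names(x$params), signif(x$params, 5), sep = "=", collapse = " "),
      sprintf("| loglik %.3f AIC %.3f BIC %.3f\n", x$loglik, x$aic, x$bic))
  invisible(x)
}

#' Fit all five parametric families
#'
#' @inheritParams fit_parametric
#' @return Named list of `parametric_model` objects (failures are dropped
#'   with a warning; at least one family must succeed).
#' @export
fit_all_families <- function(ipd) {
  fits <- list()
  for (fam in psmcea_families) {
    f <- tryCatch(fit_parametric(ipd, fam), error = function(e) {
      warning("family '", fam, "' failed to fit: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(f)) fits[[fam]] <- f
  }
  if (!length(fits)) stop("no parametric family could be fitted")
  fits
}

#' Akaike-weight model averaging ensemble
#'
#' Weights each fitted model by `exp(-delta_i/2)` where `delta_i` is its AIC
#' minus the smallest AIC, normalized to sum to one. BIC is carried in each
#' model for reporting but plays no role in the weighting.
#'
#' @param models List of `parametric_model` objects fitted on the same data.
#' @return A `bma_ensemble`: list with `models` and `weights`.
#' @export
akaike_weights <- function(models) {
  if (!length(models)) stop("need at least one model")
  aic <- vapply(models, function(m) m$aic, numeric(1))
  if (any(!is.finite(aic))) stop("non-finite AIC in ensemble")
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  structure(list(models = models, weights = w), class = "bma_ensemble")
}

#' Model-averaged survivor function
#'
#' `S(t) = sum_i w_i S_i(t)`: the weighted average of the component survivor
#' functions (averaging on the survival scale).
#'
#' @param ensemble A [akaike_weights()] ensemble.
#' @param t Times (months); vectorized.
#' @return Survival probabilities, bounded by the component survivors.
#' @export
bma_survival <- function(ensemble, t) {
  stopifnot(inherits(ensemble, "bma_ensemble"))
  comp <- vapply(ensemble$models,
                 function(m) survival_function(m$family, m$params, t),
                 numeric(length(t)))
  comp <- matrix(comp, nrow = length(t))
  # weights sum to 1 only to machine precision; clamp the convex combination
  pmin(pmax(as.numeric(comp %*% ensemble$weights), 0), 1)
}

#' Survivor grid for the partitioned survival model
#'
#' Evaluates the model-averaged survivor at monthly cycles `0..n_cycles`
#' (default 240, a 20-year horizon), extrapolating beyond follow-up.
#'
#' @param ensemble A `bma_ensemble`.
#' @param n_cycles Number of monthly cycles.
#' @return Data frame with columns `cycle` and `S`.
#' @export
survivor_grid <- function(ensemble, n_cycles = 240L) {
  cycles <- 0:n_cycles
  data.frame(cycle = cycles, S = bma_survival(ensemble, cycles))
}

#' Goodness of fit of an ensemble against a digitized curve
#'
#' @param ensemble A `bma_ensemble`.
#' @param curve A validated [digitized_curve()].
#' @return List with `sup_norm` and `mad` (deviation of the model-averaged
#'   survivor from the curve over its observed range) and `table` (one row
#'   per family: parameters, log-likelihood, AIC, BIC, weight).
#' @export
goodness_of_fit_report <- function(ensemble, curve) {
  s_hat <- bma_survival(ensemble, curve$time)
  dev <- abs(s_hat - curve$survival)
  tab <- data.frame(
    family = vapply(ensemble$models, function(m) m$family, character(1)),
    params = vapply(ensemble$models, function(m)
      paste(names(m$params), signif(m$params, 6), sep = "=", collapse = ";"),
      character(1)),
    loglik = vapply(ensemble$models, function(m) m$loglik, numeric(1)),
    aic = vapply(ensemble$models, function(m) m$aic, numeric(1)),
    bic = vapply(ensemble$models, function(m) m$bic, numeric(1)),
    weight = ensemble$weights,
    row.names = NULL)
  list(sup_norm = max(dev), mad = mean(dev), table = tab)
}
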