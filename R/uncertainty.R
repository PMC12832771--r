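#' Get or set an economic parameter by dotted path
#'
#' Paths address nested elements of an [make_parameter_set()] list, e.g.
#' `"prices.nivolumab"` or `"utilities.pfs"`. Data-frame leaves (adverse
#' events) address `"ae.intervention.cost.2"` style paths
#' (column then row).
#'
#' @param params Economic parameter list.
#' @param path Dotted path string.
#' @param value Replacement value.
#' @return The element (`param_get`) or the modified list (`param_set`).
#' @export
param_get <- function(params, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  x <- params
  for (p in parts) {
    idx <- suppressWarnings(as.integer(p))
    x <- if (is.na(idx)) x[[p]] else x[[idx]]
    if (is.null(x)) stop("unknown parameter path: '", path, "'")
  }
  x
}

#' @rdname param_get
#' @export
param_set <- function(params, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  rec <- function(x, parts) {
    key <- parts[1]
    idx <- suppressWarnings(as.integer(key))
    key <- if (is.na(idx)) key else idx
    if (is.null(x[[key]])) stop("unknown parameter path: '", path, "'")
    if (length(parts) == 1) x[[key]] <- value
    else x[[key]] <- rec(x[[key]], parts[-1])
    x
  }
  rec(params, parts)
}

#' Moment-matched gamma and beta hyperparameters
#'
#' Gamma: `shape = (mean/sd)^2`, `scale = sd^2/mean`. Beta:
#' `alpha = mean * (mean(1-mean)/sd^2 - 1)`, `beta = alpha (1-mean)/mean`;
#' the variance must satisfy `sd^2 < mean(1-mean)`.
#'
#' @param mean,sd Target moments (`mean > 0`; beta additionally requires
#'   `mean` in (0, 1)).
#' @return Named numeric of distribution parameters.
#' @export
gamma_from_moments <- function(mean, sd) {
  if (mean <= 0) stop("gamma mean must be > 0")
  if (sd < 0) stop("sd must be >= 0")
  c(shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' @rdname gamma_from_moments
#' @export
beta_from_moments <- function(mean, sd) {
  if (mean <= 0 || mean >= 1) stop("beta mean must be in (0, 1)")
  if (sd < 0) stop("sd must be >= 0")
  if (sd^2 >= mean * (1 - mean))
    stop("infeasible beta moments: sd^2 must be < mean*(1-mean)")
  a <- mean * (mean * (1 - mean) / sd^2 - 1)
  c(alpha = a, beta = a * (1 - mean) / mean)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Varies each parameter alone to its low and high value with all others at
#' base, recording the ICER at each extreme; rows come back sorted by
#' absolute spread, the tornado ordering. A model failure at an extreme
#' flags the row rather than dropping it.
#'
#' @param model_fn Function taking a named list of parameter-path overrides
#'   and returning a [icer()] result.
#' @param ranges Data frame with columns `param`, `base`, `low`, `high`
#'   (`low <= base <= high`).
#' @return Data frame with `param`, `icer_low`, `icer_high`, `spread`,
#'   `failed`.
#' @export
one_way_sa <- function(model_fn, ranges) {
  stopifnot(all(c("param", "base", "low", "high") %in% names(ranges)))
  if (any(ranges$low > ranges$base | ranges$base > ranges$high))
    stop("each range must satisfy low <= base <= high")
  eval_at <- function(param, value) {
    tryCatch(model_fn(stats::setNames(list(value), param))$icer,
             error = function(e) NA_real_)
  }
  rows <- lapply(seq_len(nrow(ranges)), function(i) {
    lo <- eval_at(ranges$param[i], ranges$low[i])
    hi <- eval_at(ranges$param[i], ranges$high[i])
    data.frame(param = ranges$param[i], icer_low = lo, icer_high = hi,
               spread = abs(hi - lo), failed = is.na(lo) || is.na(hi))
  })
  out <- do.call(rbind, rows)
  out[order(-out$spread), , drop = FALSE]
}

#' Two-way sensitivity analysis over a price grid
#'
#' Full factorial evaluation of two parameters; each cell records the ICER
#' and whether the intervention is cost-effective at `wtp`.
#'
#' @param model_fn As in [one_way_sa()].
#' @param paramA,paramB Parameter paths.
#' @param gridA,gridB Numeric vectors of values (length >= 2).
#' @param wtp Willingness-to-pay for the cost-effective flag.
#' @return Data frame with `valueA`, `valueB`, `icer`, `cost_effective`.
#' @export
two_way_sa <- function(model_fn, paramA, gridA, paramB, gridB, wtp) {
  if (length(gridA) < 2 || length(gridB) < 2)
    stop("each grid needs at least 2 values")
  grid <- expand.grid(valueA = gridA, valueB = gridB)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ce <- model_fn(stats::setNames(list(grid$valueA[i], grid$valueB[i]),
                                   c(paramA, paramB)))
    nmb <- net_monetary_benefit(ce, wtp)
    data.frame(valueA = grid$valueA[i], valueB = grid$valueB[i],
               icer = ce$icer, cost_effective = nmb > 0)
  })
  do.call(rbind, res)
}

#' Probabilistic sensitivity analysis specification
#'
#' @param params Data frame with columns `param` (path), `base`, `dist`
#'   (`"gamma"` for costs, `"beta"` for utilities) and optionally `sd`
#'   (default 20% of base).
#' @param n_draws Number of Monte Carlo draws (default 1000).
#' @param seed Integer seed.
#' @return An object of class `psa_spec`.
#' @export
psa_spec <- function(params, n_draws = 1000L, seed = 1L) {
  stopifnot(all(c("param", "base", "dist") %in% names(params)))
  if (n_draws < 1) stop("n_draws must be >= 1")
  if (!all(params$dist %in% c("gamma", "beta")))
    stop("dist must be 'gamma' or 'beta'")
  if (is.null(params$sd)) params$sd <- 0.2 * params$base
  structure(list(params = params, n_draws = as.integer(n_draws),
                 seed = as.integer(seed)),
            class = "psa_spec")
}

#' Probabilistic sensitivity analysis
#'
#' Draws every parameter simultaneously from its moment-matched gamma
#' (costs) or beta (utilities) distribution and re-evaluates the model; an
#' `sd` of zero pins a parameter at its base value. Draws are reproducible
#' for a fixed seed.
#'
#' @param model_fn As in [one_way_sa()].
#' @param spec A [psa_spec()].
#' @return Data frame with one row per draw: `draw`, `dcost`, `dqaly`.
#' @export
psa <- function(model_fn, spec) {
  stopifnot(inherits(spec, "psa_spec"))
  p <- spec$params
  set.seed(spec$seed)
  draws <- matrix(NA_real_, nrow = spec$n_draws, ncol = nrow(p))
  for (j in seq_len(nrow(p))) {
    if (p$sd[j] == 0) {
      draws[, j] <- p$base[j]
    } else if (p$dist[j] == "gamma") {
      g <- gamma_from_moments(p$base[j], p$sd[j])
      draws[, j] <- stats::rgamma(spec$n_draws, shape = g["shape"],
                                  scale = g["scale"])
    } else {
      b <- beta_from_moments(p$base[j], p$sd[j])
      draws[, j] <- stats::rbeta(spec$n_draws, b["alpha"], b["beta"])
    }
  }
  out <- lapply(seq_len(spec$n_draws), function(i) {
    ce <- model_fn(stats::setNames(as.list(draws[i, ]), p$param))
    data.frame(draw = i, dcost = ce$dcost, dqaly = ce$deffect)
  })
  do.call(rbind, out)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the exact fraction of PSA draws with
#' positive net monetary benefit.
#'
#' @param draws [psa()] output (columns `dcost`, `dqaly`).
#' @param wtp_grid Numeric vector of thresholds.
#' @return Data frame with `wtp`, `probability`.
#' @export
ceac <- function(draws, wtp_grid) {
  if (nrow(draws) < 1) stop("need at least one draw")
  data.frame(
    wtp = wtp_grid,
    probability = vapply(wtp_grid, function(w)
      mean(w * draws$dqaly - draws$dcost > 0), numeric(1)))
}

#' Price multiplier at which the ICER meets a threshold
#'
#' Bisection on a price multiplier applied to the selected drug prices
#' (single drug or several simultaneously) until the ICER is within
#' `tol` (relative) of the willingness-to-pay. When net monetary benefit
#' does not change sign over the bounds, the regimen is reported as always
#' or never cost-effective in range.
#'
#' @param model_fn As in [one_way_sa()].
#' @param price_paths Character vector of price parameter paths the
#'   multiplier scales together.
#' @param base_prices Numeric vector of the base prices, same order.
#' @param wtp Willingness-to-pay threshold.
#' @param bounds Multiplier search interval (default `c(0.01, 3)`).
#' @param tol Relative ICER tolerance (default 1e-4).
#' @return List with `multiplier`, `achieved_icer`, `status`
#'   (`"solved"`, `"always"`, `"never"`).
#' @export
price_threshold <- function(model_fn, price_paths, base_prices, wtp,
                            bounds = c(0.01, 3), tol = 1e-4) {
  stopifnot(length(price_paths) == length(base_prices))
  eval_m <- function(m)
    model_fn(stats::setNames(as.list(base_prices * m), price_paths))
  g <- function(m) net_monetary_benefit(eval_m(m), wtp)  # decreasing in m
  g_lo <- g(bounds[1]); g_hi <- g(bounds[2])
  if (g_lo > 0 && g_hi > 0)
    return(list(multiplier = NA_real_, achieved_icer = eval_m(bounds[2])$icer,
                status = "always"))
  if (g_lo < 0 && g_hi < 0)
    return(list(multiplier = NA_real_, achieved_icer = eval_m(bounds[1])$icer,
                status = "never"))
  lo <- bounds[1]; hi <- bounds[2]
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    ce <- eval_m(mid)
    if (!is.na(ce$icer) && abs(ce$icer - wtp) / wtp < tol) break
    if (net_monetary_benefit(ce, wtp) * g_lo > 0) lo <- mid else hi <- mid
  }
  list(multiplier = mid, achieved_icer = ce$icer, status = "solved")
}
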