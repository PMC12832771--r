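#' Digitized Kaplan-Meier curve
#'
#' Container for time-survival coordinates extracted from a published KM
#' figure. Times are months, survival is a probability; construction checks
#' the product-limit invariants (first point (0, 1), strictly increasing
#' times, non-increasing survival). Use [validate_curve()] to repair small
#' digitization noise before construction-level checks would reject it.
#'
#' @param time Numeric vector of times (months, >= 0).
#' @param survival Numeric vector of survival probabilities in [0, 1].
#' @param arm,endpoint Optional labels.
#' @param check Run invariant checks (set `FALSE` internally when a repair
#'   step will follow).
#' @return A data frame of class `digitized_curve` with columns `time`,
#'   `survival` and attributes `arm`, `endpoint`.
#' @export
digitized_curve <- function(time, survival, arm = "", endpoint = "",
                            check = TRUE) {
  stopifnot(length(time) == length(survival))
  out <- data.frame(time = as.numeric(time), survival = as.numeric(survival))
  if (check) {
    if (nrow(out) < 1L) stop("curve needs at least one point")
    if (any(out$time < 0)) stop("curve times must be >= 0")
    if (any(diff(out$time) <= 0)) stop("curve times must be strictly increasing")
    if (any(out$survival < 0 | out$survival > 1))
      stop("survival must lie in [0, 1]")
    if (out$time[1] != 0 || out$survival[1] != 1)
      stop("curve must start at (0, 1); use validate_curve() to insert it")
    if (any(diff(out$survival) > 0))
      stop("survival must be non-increasing; use validate_curve() to repair")
  }
  attr(out, "arm") <- arm
  attr(out, "endpoint") <- endpoint
  class(out) <- c("digitized_curve", "data.frame")
  out
}

#' Number-at-risk table
#'
#' @param time Numeric vector of grid times (months, strictly increasing).
#' @param n_at_risk Non-negative, non-increasing integer counts; the first
#'   must be positive.
#' @return A data frame of class `risk_table`.
#' @export
risk_table <- function(time, n_at_risk) {
  stopifnot(length(time) == length(n_at_risk))
  if (any(diff(time) <= 0)) stop("risk-table times must be strictly increasing")
  if (any(n_at_risk < 0) || any(n_at_risk != round(n_at_risk)))
    stop("n_at_risk must be non-negative integers")
  if (any(diff(n_at_risk) > 0)) stop("n_at_risk must be non-increasing")
  if (n_at_risk[1] <= 0) stop("initial number at risk must be positive")
  out <- data.frame(time = as.numeric(time), n_at_risk = as.integer(n_at_risk))
  class(out) <- c("risk_table", "data.frame")
  out
}

#' Validate and repair a digitized curve
#'
#' Digitization introduces small monotonicity violations (a later coordinate
#' read slightly above an earlier one). Violations of at most `tolerance`
#' are repaired by isotonic clipping to the running minimum; larger ones are
#' rejected, naming the offending point. A missing (0, 1) origin is
#' inserted.
#'
#' @param curve A [digitized_curve()] or plain data frame with `time` and
#'   `survival` columns.
#' @param tolerance Largest upward survival step considered digitization
#'   noise (probability units).
#' @return A valid `digitized_curve`.
#' @export
validate_curve <- function(curve, tolerance = 0.01) {
  if (nrow(curve) < 2L && !(nrow(curve) >= 1L && curve$time[1] == 0))
    stop("curve needs at least two points (or an explicit origin)")
  time <- curve$time
  surv <- curve$survival
  if (any(time < 0)) stop("curve times must be >= 0")
  if (any(diff(time) <= 0)) stop("curve times must be strictly increasing")
  if (any(surv < 0 | surv > 1)) stop("survival must lie in [0, 1]")
  if (time[1] != 0) {
    if (surv[1] > 1) stop("survival must lie in [0, 1]")
    time <- c(0, time)
    surv <- c(1, surv)
  } else if (surv[1] != 1) {
    if (1 - surv[1] > tolerance)
      stop("survival at time 0 is ", surv[1], "; exceeds tolerance ", tolerance)
    surv[1] <- 1
  }
  runmin <- cummin(surv)
  excess <- surv - runmin
  if (any(excess > tolerance)) {
    k <- which(excess > tolerance)[1]
    stop("non-monotone survival at time ", time[k], " (", surv[k],
         " after ", runmin[k], "); exceeds tolerance ", tolerance)
  }
  digitized_curve(time, runmin,
                  arm = attr(curve, "arm") %||% "",
                  endpoint = attr(curve, "endpoint") %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Product-limit (Kaplan-Meier) estimate of IPD
#'
#' Standard product-limit estimator via [survival::survfit()]; ties are
#' handled with events preceding censorings at equal times. The returned
#' curve has the (0, 1) origin followed by coordinates at each event time.
#'
#' @param ipd Data frame with columns `time` (> 0) and `event` (1/0).
#' @param arm,endpoint Labels attached to the returned curve.
#' @return A [digitized_curve()].
#' @export
km_estimate <- function(ipd, arm = "", endpoint = "") {
  if (nrow(ipd) == 0L) stop("ipd must contain at least one row")
  if (!all(ipd$event %in% c(0, 1))) stop("event must be 0/1")
  if (any(ipd$time <= 0)) stop("times must be positive")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  keep <- fit$n.event > 0
  digitized_curve(c(0, fit$time[keep]), c(1, fit$surv[keep]),
                  arm = arm, endpoint = endpoint)
}

#' Reconstruct pseudo individual patient data from a KM curve
#'
#' Guyot-style iterative algorithm: within each number-at-risk interval it
#' guesses the number censored, spreads those censorings uniformly over the
#' interval, derives integer event counts at each curve coordinate from the
#' survival drops, and adjusts the censoring guess until the implied number
#' at risk at the next grid time matches the table. After the last risk-table
#' entry the censoring rate of the preceding interval is carried forward
#' (or, when `total_events` is supplied, censoring is chosen to hit that
#' event count where feasible). Subjects still at risk at the last curve
#' coordinate are censored there.
#'
#' @param curve A validated [digitized_curve()].
#' @param risk A [risk_table()] whose times span the curve.
#' @param total_events Optional integer: reported total number of events,
#'   matched exactly where feasible.
#' @param max_iter Iteration cap per interval.
#' @return A data frame of class `reconstructed_ipd` with columns `time`,
#'   `event`, plus attributes `diagnostics` (per-interval target vs achieved
#'   number at risk) and `fit_error` (sup-norm of the product-limit estimate
#'   of the output against the input coordinates).
#' @export
reconstruct_ipd <- function(curve, risk, total_events = NULL, max_iter = 50L) {
  curve <- validate_curve(curve)
  if (!inherits(risk, "risk_table")) risk <- risk_table(risk$time, risk$n_at_risk)
  if (risk$time[1] > curve$time[1])
    stop("risk table must start at or before the first curve time")
  tS <- curve$time
  S <- curve$survival
  K <- length(tS)
  trisk <- risk$time
  nrisk <- risk$n_at_risk
  nint <- length(trisk)

  # curve-point index range [lower_i, upper_i] per risk interval
  lower <- upper <- integer(nint)
  for (i in seq_len(nint)) {
    lo <- if (i < nint) which(tS >= trisk[i] & tS < trisk[i + 1])
          else which(tS >= trisk[i])
    lower[i] <- if (length(lo)) min(lo) else NA_integer_
    upper[i] <- if (length(lo)) max(lo) else NA_integer_
  }

  n <- nrisk[1]
  d <- integer(K)          # events at each curve coordinate
  cens_times <- numeric(0) # censoring times
  KM <- numeric(K)         # running product-limit estimate at coordinates
  n_hat <- n               # at risk entering the next coordinate
  KM_prev <- 1
  last_done <- 0L          # last coordinate processed
  achieved <- nrisk        # implied n at risk at each grid time
  interval_rate <- 0       # censoring rate of the last constrained interval

  process_interval <- function(ks, ncens, n_start, KM_start, t_lo, t_hi) {
    # spread ncens censorings uniformly on (t_lo, t_hi], walk coordinates ks
    ct <- if (ncens > 0) t_lo + (seq_len(ncens) - 0.5) / ncens * (t_hi - t_lo)
          else numeric(0)
    nh <- n_start; km <- KM_start
    dd <- integer(length(ks)); used <- 0L
    for (j in seq_along(ks)) {
      k <- ks[j]
      # censorings strictly before this coordinate leave the risk set first
      # (ties at the coordinate itself resolve events-before-censorings)
      before <- max(0L, min(sum(ct < tS[k]) - used, nh))
      used <- used + before
      nh <- nh - before
      ev <- if (km > 0) round(nh * (1 - S[k] / km)) else 0
      ev <- max(0L, min(as.integer(ev), nh))
      dd[j] <- ev
      km <- if (nh > 0) km * (1 - ev / nh) else km
      nh <- nh - ev
    }
    rest <- min(ncens - used, nh)   # censorings after the last coordinate
    used <- used + rest
    nh <- nh - rest
    list(d = dd, n_end = nh, KM_end = km, cens_times = ct[seq_len(used)],
         unused = ncens - used)
  }

  for (i in seq_len(max(1L, nint - 1L))) {
    if (i > nint - 1L) break
    ks <- if (!is.na(lower[i])) lower[i]:upper[i] else integer(0)
    S_lo <- if (length(ks)) S[max(ks)] else KM_prev
    S_at_next <- step_surv(tS, S, trisk[i + 1])
    S_at_cur <- step_surv(tS, S, trisk[i])
    # first guess: censorings explain the gap between expected and tabulated n
    guess <- round(n_hat * (if (S_at_cur > 0) S_at_next / S_at_cur else 1)) -
      nrisk[i + 1]
    guess <- max(0L, min(as.integer(guess), n_hat))
    prev_guess <- -1L
    for (iter in seq_len(max_iter)) {
      res <- process_interval(ks, guess, n_hat, KM_prev, trisk[i], trisk[i + 1])
      gap <- res$n_end - nrisk[i + 1]
      if (gap == 0L || guess == prev_guess) break
      prev_guess <- guess
      guess <- max(0L, min(guess + gap, n_hat))
    }
    if (length(ks)) d[ks] <- res$d
    cens_times <- c(cens_times, res$cens_times)
    achieved[i + 1] <- res$n_end
    interval_rate <- if (n_hat > 0)
      guess / (n_hat * (trisk[i + 1] - trisk[i])) else 0
    n_hat <- res$n_end
    KM_prev <- res$KM_end
    last_done <- if (length(ks)) max(ks) else last_done
  }

  # tail: curve coordinates after the last risk-table time
  tail_ks <- which(seq_len(K) > last_done & tS >= trisk[nint] - 1e-12)
  if (length(tail_ks) || n_hat > 0) {
    t_lo <- trisk[nint]
    t_hi <- max(tS)
    if (!is.null(total_events)) {
      # event count decreases as tail censoring grows; smallest censoring
      # count whose event total does not overshoot the target
      target_tail_events <- max(0L, as.integer(total_events) - sum(d))
      res <- NULL
      for (ncens in 0:max(0L, n_hat)) {
        res <- process_interval(tail_ks, ncens, n_hat, KM_prev, t_lo, t_hi)
        if (sum(res$d) <= target_tail_events) break
      }
    } else {
      ncens <- min(n_hat, as.integer(round(
        interval_rate * n_hat * max(0, t_hi - t_lo))))
      res <- process_interval(tail_ks, ncens, n_hat, KM_prev, t_lo, t_hi)
    }
    if (length(tail_ks)) d[tail_ks] <- res$d
    cens_times <- c(cens_times, res$cens_times)
    n_hat <- res$n_end
  }

  if (sum(d) == 0 && any(S < 1) && max(nrisk) >= 1) {
    bad <- which(S < 1)[1]
    stop("reconstruction infeasible: curve drops at t=", tS[bad],
         " but risk counts admit no events")
  }

  # censorings beyond the plotted range are recorded at the last coordinate
  cens_times <- pmin(cens_times, max(tS))
  times <- c(rep(tS, d), cens_times, rep(max(tS), n_hat))
  events <- c(rep(1L, sum(d)), rep(0L, length(cens_times) + n_hat))
  times <- pmax(times, .Machine$double.eps)
  ipd <- data.frame(time = times, event = events)
  o <- order(ipd$time, -ipd$event)
  ipd <- ipd[o, , drop = FALSE]
  rownames(ipd) <- NULL

  if (nrow(ipd) != nrisk[1])
    stop("reconstruction infeasible: produced ", nrow(ipd),
         " subjects for an initial risk set of ", nrisk[1])

  km_out <- km_estimate(ipd)
  fit_err <- max(abs(step_surv(km_out$time, km_out$survival, tS) - S))
  diagnostics <- data.frame(time = trisk, target_n = nrisk,
                            achieved_n = achieved)
  structure(ipd,
            diagnostics = diagnostics,
            fit_error = fit_err,
            total_events = sum(d),
            class = c("reconstructed_ipd", "data.frame"))
}

# right-continuous step-function evaluation of a KM curve
step_surv <- function(time, surv, at) {
  idx <- findInterval(at, time)
  ifelse(idx == 0, 1, surv[pmax(idx, 1)])
}
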