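#' Partitioned survival model configuration
#'
#' The model runs on a fixed one-month cycle. `pfs2_exit_rate` is the
#' per-month hazard of leaving the second progression-free state (PFS2) for
#' progressive disease; the default corresponds to a median PFS2 sojourn of
#' 6 months. `Inf` sends all post-progression occupancy straight to PD;
#' `0` keeps it all in PFS2.
#'
#' @param n_cycles Horizon in monthly cycles (default 240 = 20 years).
#' @param pfs2_exit_rate Per-month exit hazard from PFS2 (>= 0, may be Inf).
#' @param half_cycle_correction Average adjacent-cycle occupancies when
#'   accruing time (trapezoid rule) instead of end-of-cycle accrual.
#' @return An object of class `psm_config`.
#' @export
psm_config <- function(n_cycles = 240L, pfs2_exit_rate = log(2) / 6,
                       half_cycle_correction = FALSE) {
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (pfs2_exit_rate < 0) stop("pfs2_exit_rate must be >= 0")
  structure(list(n_cycles = as.integer(n_cycles),
                 pfs2_exit_rate = pfs2_exit_rate,
                 half_cycle_correction = isTRUE(half_cycle_correction)),
            class = "psm_config")
}

as_surv_grid <- function(S, n_cycles) {
  if (is.data.frame(S)) S <- S$S
  if (length(S) < n_cycles + 1)
    stop("survivor grid shorter than the model horizon (need ",
         n_cycles + 1, " cycles, got ", length(S), ")")
  S <- S[seq_len(n_cycles + 1)]
  if (abs(S[1] - 1) > 1e-9) stop("survivor grid must start at S(0) = 1")
  if (any(S < -1e-12 | S > 1 + 1e-12)) stop("survivor values outside [0, 1]")
  pmin(pmax(S, 0), 1)
}

#' Per-cycle state occupancy from OS and PFS survivor grids
#'
#' Partitioned-survival bookkeeping: `PFS(t) = min(S_pfs(t), S_os(t))`
#' (independently extrapolated curves may cross; the cap is the standard
#' repair and is flagged in the result), `Death(t) = 1 - S_os(t)`, and the
#' alive-but-progressed remainder `S_os(t) - PFS(t)` is split between PFS2
#' and PD by an exponential-sojourn convolution: mass entering PFS2 at
#' cycle `s` still occupies it at cycle `t >= s` with probability
#' `exp(-pfs2_exit_rate * (t - s + 1))` (one exit opportunity per completed
#' cycle), truncated so PFS2 never exceeds the remainder; PD takes the rest.
#'
#' @param S_pfs,S_os Survivor grids: numeric vectors over cycles
#'   `0..n_cycles`, or data frames from [survivor_grid()].
#' @param config A [psm_config()].
#' @return A data frame of class `state_trace` with columns `cycle`, `pfs`,
#'   `pfs2`, `pd`, `death`, `incident_deaths`, `incident_progressions`;
#'   attribute `pfs_capped` flags cycles where `S_pfs > S_os` was repaired.
#' @export
compute_occupancy <- function(S_pfs, S_os, config = psm_config()) {
  n <- config$n_cycles
  spfs <- as_surv_grid(S_pfs, n)
  sos <- as_surv_grid(S_os, n)
  capped <- spfs > sos + 1e-12
  pfs <- pmin(spfs, sos)
  death <- 1 - sos
  rem <- sos - pfs
  prog <- c(0, pmax(0, -diff(pfs)))  # incident progressions per cycle
  decay <- exp(-config$pfs2_exit_rate)
  if (config$pfs2_exit_rate == Inf) decay <- 0
  u <- numeric(n + 1)                # unconstrained PFS2 convolution
  for (t in seq_len(n)) u[t + 1] <- (u[t] + prog[t + 1]) * decay
  pfs2 <- pmin(u, rem)
  pd <- rem - pfs2
  trace <- data.frame(cycle = 0:n, pfs = pfs, pfs2 = pfs2, pd = pd,
                      death = death,
                      incident_deaths = c(0, pmax(0, diff(death))),
                      incident_progressions = prog)
  check_trace(trace)
  attr(trace, "pfs_capped") <- which(capped) - 1L
  class(trace) <- c("state_trace", "data.frame")
  trace
}

check_trace <- function(trace) {
  tot <- trace$pfs + trace$pfs2 + trace$pd + trace$death
  if (any(abs(tot - 1) > 1e-9))
    stop("state occupancies do not sum to 1 (max deviation ",
         format(max(abs(tot - 1))), ")")
  if (any(trace$pfs < 0 | trace$pfs2 < 0 | trace$pd < 0 | trace$death < 0))
    stop("negative state occupancy")
  if (any(diff(trace$death) < -1e-12)) stop("death occupancy must not decrease")
  if (any(diff(trace$pfs) > 1e-12)) stop("PFS occupancy must not increase")
  invisible(TRUE)
}

#' Discounted life-years on a state trace
#'
#' Accrues `occupancy * (1/12)` years per monthly cycle over the alive
#' states, discounted at an annual rate with the end-of-cycle convention
#' `(1 + r)^(-t/12)`; with the half-cycle correction, adjacent-cycle
#' occupancies are averaged (trapezoid).
#'
#' @param trace A [compute_occupancy()] trace.
#' @param discount_rate Annual discount rate (>= 0).
#' @param alive_states States counted as alive.
#' @param half_cycle_correction Trapezoid accrual.
#' @return Discounted life-years.
#' @export
life_years <- function(trace, discount_rate = 0,
                       alive_states = c("pfs", "pfs2", "pd"),
                       half_cycle_correction = FALSE) {
  if (discount_rate < 0) stop("discount_rate must be >= 0")
  occ <- rowSums(trace[, alive_states, drop = FALSE])
  occ <- cycle_accrual(occ, half_cycle_correction)
  t <- trace$cycle[-1]
  sum(occ * discount_factor(discount_rate, t)) / 12
}

# occupancy credited to each completed cycle 1..n
cycle_accrual <- function(occ, half_cycle_correction) {
  n <- length(occ) - 1
  if (half_cycle_correction) (occ[1:n] + occ[2:(n + 1)]) / 2
  else occ[2:(n + 1)]
}
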