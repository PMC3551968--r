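#' Triangular coupling-strength schedule
#'
#' The coupling strength ramps linearly from 0 up to `K_peak` and back to 0
#' over the schedule duration (a triangular signal), optionally preceded by
#' a zero-coupling hold window.  With `hold = 0` the schedule is the pure
#' triangle: `K(0) = K(duration) = 0` and `K(duration/2) = K_peak`.
#'
#' @param K_peak peak dimensionless coupling strength (>= 0)
#' @param duration total schedule duration (ns, > 0)
#' @param hold initial window with `K = 0` (ns, default 0); the triangle
#'   then spans `[hold, duration]`
#' @return object of class `coupling_schedule`; use [schedule_K()] to
#'   evaluate it
#' @export
coupling_schedule <- function(K_peak, duration, hold = 0) {
  if (K_peak < 0) stop("`K_peak` must be non-negative", call. = FALSE)
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  if (hold < 0 || hold >= duration) {
    stop("`hold` must lie in [0, duration)", call. = FALSE)
  }
  structure(list(K_peak = K_peak, duration = duration, hold = hold),
            class = "coupling_schedule")
}

#' Evaluate a coupling schedule
#'
#' @param schedule a [coupling_schedule()]
#' @param t time in ns (vectorised)
#' @return dimensionless coupling strength `K_c(t)` (0 outside the schedule)
#' @export
schedule_K <- function(schedule, t) {
  stopifnot(inherits(schedule, "coupling_schedule"))
  span <- schedule$duration - schedule$hold
  mid <- schedule$hold + span / 2
  K <- ifelse(t <= mid,
              (t - schedule$hold) / (span / 2),
              (schedule$duration - t) / (span / 2)) * schedule$K_peak
  pmax(0, K)
}

#' Oscillation phases from tunneling-event times
#'
#' The local maxima of a member's NP potential are its pre-reset peaks, i.e.
#' exactly the logged tunneling-event times, so the phase is linearly
#' interpolated between consecutive events:
#' `phi_i(t) = 2*pi*(t - t_k)/(t_{k+1} - t_k)` for `t` in `[t_k, t_{k+1})`.
#' Outside a member's first/last event (or for members with fewer than two
#' events) the phase is undefined and returned as `NA`.
#'
#' @param spikes a `spike_train`
#' @param grid sampling times (ns) within the simulation window
#' @return object of class `phase_series`: list with `grid` and `phi`
#'   (`length(grid) x N` matrix of phases in `[0, 2*pi)`, `NA` where
#'   undefined)
#' @export
extract_phases <- function(spikes, grid) {
  stopifnot(inherits(spikes, "spike_train"))
  if (any(grid < 0) || any(grid > spikes$duration)) {
    stop("`grid` must lie within the simulation window", call. = FALSE)
  }
  phi <- matrix(NA_real_, nrow = length(grid), ncol = spikes$N)
  for (i in seq_len(spikes$N)) {
    tk <- spikes$times[[i]]
    if (length(tk) < 2L) next
    idx <- findInterval(grid, tk)
    ok <- idx >= 1L & grid < tk[length(tk)]
    j <- idx[ok]
    phi[ok, i] <- 2 * pi * (grid[ok] - tk[j]) / (tk[j + 1L] - tk[j])
  }
  structure(list(grid = grid, phi = phi), class = "phase_series")
}

#' Complex (Kuramoto) order parameter
#'
#' `z(t) = mean(exp(1i * phi_j(t)))` over the members whose phase is defined
#' at `t`.  `|z| = 1` means full synchronization; for many uncorrelated
#' oscillators `|z|` tends to 0.  Times at which fewer than `min_defined`
#' members have a defined phase are masked (`NA`).
#'
#' @param phases a [extract_phases()] result
#' @param min_defined minimum number of defined phases required (default 2)
#' @return data.frame with `time`, `re`, `im`, `mod` (`Mod(z)`), and
#'   `n_defined`
#' @examples
#' # two members a quarter-cycle apart: |z| = sqrt(2)/2
#' @export
order_parameter <- function(phases, min_defined = 2L) {
  stopifnot(inherits(phases, "phase_series"))
  zmat <- exp(1i * phases$phi)
  n_def <- rowSums(!is.na(phases$phi))
  z <- rowMeans(zmat, na.rm = TRUE)
  z[n_def < min_defined] <- NA_complex_
  data.frame(time = phases$grid, re = Re(z), im = Im(z), mod = Mod(z),
             n_defined = n_def)
}

#' Synchronization experiment under a coupling schedule
#'
#' Simulates an ensemble at constant applied potential while the coupling
#' resistance follows `r_c(t) = coupling_resistance(K_c(t))` for a
#' triangular [coupling_schedule()].  All NP potentials start at zero, so
#' the ensemble is fully synchronized at `t = 0`; it desynchronizes while
#' `K_c` is small (quickly for heterogeneous ensembles, only through thermal
#' noise for identical ones), synchronizes when the coupling is strong, and
#' desynchronizes again as `K_c` returns to zero.
#'
#' @param ensemble an [sample_ensemble()] object
#' @param V constant applied potential (mV)
#' @param schedule a [coupling_schedule()]; its duration must equal the
#'   simulation duration
#' @param cfg a [sim_config()]
#' @param grid_dt sampling interval of the order parameter (ns, default 1)
#' @return object of class `sync_result`: list with `series` (data.frame
#'   `time`, `K`, `re`, `im`, `mod`, `n_defined`), `spikes`, `schedule`
#' @export
run_sync_experiment <- function(ensemble, V, schedule, cfg, grid_dt = 1) {
  stopifnot(inherits(schedule, "coupling_schedule"), inherits(cfg, "sim_config"))
  if (abs(schedule$duration - cfg$duration) > 1e-9) {
    stop("schedule duration must equal the simulation duration", call. = FALSE)
  }
  rc_fun <- function(t) coupling_resistance(schedule_K(schedule, t), ensemble)
  run <- run_rset(ensemble, V, cfg, r_c = rc_fun)
  grid <- seq(0, cfg$duration, by = grid_dt)
  op <- order_parameter(extract_phases(run$spikes, grid))
  op$K <- schedule_K(schedule, grid)
  structure(
    list(series = op[, c("time", "K", "re", "im", "mod", "n_defined")],
         spikes = run$spikes, schedule = schedule, run = run),
    class = "sync_result"
  )
}

#' @export
print.sync_result <- function(x, ...) {
  ok <- is.finite(x$series$mod)
  cat(sprintf(
    "sync experiment: K_peak = %g over %g ns; |z| range %.3f..%.3f (%d sampled times)\n",
    x$schedule$K_peak, x$schedule$duration,
    if (any(ok)) min(x$series$mod[ok]) else NA,
    if (any(ok)) max(x$series$mod[ok]) else NA, sum(ok)))
  invisible(x)
}
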