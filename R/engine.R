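#' Simulation configuration for the mixed continuum-Monte Carlo engine
#'
#' Between tunneling events every NP potential follows the deterministic
#' charging equation, integrated with the exact exponential update over fixed
#' steps `dt`.  At the end of each step the energy change of a candidate
#' tunneling event is evaluated at the post-charging potential and a
#' stochastic decision is drawn per member (at most one event per member per
#' step).
#'
#' Two decision rules are available:
#' \describe{
#'   \item{`"metropolis"` (default)}{accept with probability
#'     `min(1, exp(dE/kT))`.  Above threshold the electron tunnels in the
#'     same step in which it becomes energetically favourable, so at low
#'     temperature the spike period reproduces the deterministic closed form
#'     [deterministic_period()] to within one step; below threshold the
#'     Boltzmann factor gives the thermal smearing.}
#'   \item{`"kmc"`}{kinetic Monte Carlo: accept with probability
#'     `1 - exp(-Gamma(dE)*dt)` using the orthodox-theory rate
#'     [tunneling_rate()].  Physically rate-faithful, but the finite tunnel
#'     resistance adds a stochastic firing lag above threshold.}
#' }
#'
#' @param duration total simulated time (ns, > 0)
#' @param dt time step (ns); `NULL` (default) resolves to `tau_min/100`,
#'   where `tau_min` is the smallest member time constant.  Steps coarser
#'   than `tau_min/50` trigger an accuracy warning.
#' @param temperature temperature (K), default 5
#' @param seed optional integer seed for the run's RNG stream
#' @param record_traces record the NP potentials along the run
#' @param trace_stride record every `trace_stride`-th step
#' @param rule tunneling decision rule, see Details
#' @return object of class `sim_config`
#' @export
sim_config <- function(duration, dt = NULL, temperature = 5, seed = NULL,
                       record_traces = FALSE, trace_stride = 10L,
                       rule = c("metropolis", "kmc")) {
  if (!is.numeric(duration) || length(duration) != 1L || duration < 0) {
    stop("`duration` must be a non-negative time in ns", call. = FALSE)
  }
  if (!is.null(dt) && (!is.numeric(dt) || length(dt) != 1L || dt <= 0)) {
    stop("`dt` must be a positive time step in ns (or NULL)", call. = FALSE)
  }
  if (temperature <= 0) stop("`temperature` must be positive", call. = FALSE)
  rule <- match.arg(rule)
  structure(
    list(duration = duration, dt = dt, temperature = temperature,
         seed = seed, record_traces = isTRUE(record_traces),
         trace_stride = max(1L, as.integer(trace_stride)), rule = rule),
    class = "sim_config"
  )
}

#' Common-node potential of a resistively coupled ensemble
#'
#' When the ensemble is coupled through a common resistance `r_c` between
#' the input electrode (potential `V`) and the members' charging
#' resistances, current conservation at the star point gives
#' `V_n = (V/r_c + sum(V_j/r_j)) / (1/r_c + sum(1/r_j))`.
#' At `r_c = 0` the node is pinned to the source: `V_n = V`.
#'
#' @param V input electrode potential (mV)
#' @param V_members per-member NP potentials (mV)
#' @param r_members per-member charging resistances (GOhm)
#' @param r_c coupling resistance (GOhm, >= 0)
#' @return node potential in mV
#' @examples
#' node_potential(100, c(0, 100), c(10, 10), 10)  # ~66.67 mV
#' @export
node_potential <- function(V, V_members, r_members, r_c) {
  if (r_c < 0) stop("`r_c` must be non-negative", call. = FALSE)
  if (r_c == 0) return(V)
  g <- 1 / r_members
  (V / r_c + sum(V_members * g)) / (1 / r_c + sum(g))
}

#' Dimensionless coupling strength of a resistively coupled ensemble
#'
#' `K_c = N * r_c / mean(r)`.  In the homogeneous-`r` case the coupled
#' charging equation can be rewritten as
#' `dV_i/dt = [(V - V_i) + (K_c/N) * sum_j (V_j - V_i)] / (r C (1 + K_c))`,
#' i.e. `K_c/N` is the usual all-to-all (Kuramoto-style) coupling
#' coefficient.  `K_c = 0` at `r_c = 0` and `K_c` is linear in `r_c`.
#'
#' @param r_c coupling resistance (GOhm, >= 0)
#' @param ensemble an [sample_ensemble()] object
#' @return dimensionless coupling strength
#' @seealso [coupling_resistance()] for the inverse map
#' @export
coupling_strength <- function(r_c, ensemble) {
  stopifnot(inherits(ensemble, "rset_ensemble"))
  if (any(r_c < 0)) stop("`r_c` must be non-negative", call. = FALSE)
  nrow(ensemble) * r_c / mean_charging_resistance(ensemble)
}

#' Coupling resistance realising a given coupling strength
#'
#' Inverse of [coupling_strength()]: `r_c = K_c * mean(r) / N`.  Single
#' source of truth for converting coupling schedules into resistances.
#'
#' @param K_c dimensionless coupling strength (>= 0); vectorised
#' @param ensemble an [sample_ensemble()] object
#' @return coupling resistance in GOhm
#' @export
coupling_resistance <- function(K_c, ensemble) {
  stopifnot(inherits(ensemble, "rset_ensemble"))
  if (any(K_c < 0)) stop("`K_c` must be non-negative", call. = FALSE)
  K_c * mean_charging_resistance(ensemble) / nrow(ensemble)
}

#' Run the mixed continuum-Monte Carlo simulation
#'
#' Simulates an ensemble driven by an input potential, optionally coupled
#' through a common resistance.  All NP potentials start at zero.  Per step:
#' the driving potential is frozen (the input, or the common-node potential
#' [node_potential()] if coupled), every member charges exponentially toward
#' it, the tunneling energy gain is evaluated at the post-charging potential,
#' and a per-member stochastic tunneling decision is drawn (see
#' [sim_config()]).  Events reset the member by `-2*V_th` and are logged at
#' the end of the step (time resolution = `dt`).  A single RNG stream is
#' used, member decisions drawn in member order each step, so runs are
#' bit-reproducible under a fixed seed.
#'
#' @param ensemble an [sample_ensemble()] object
#' @param input applied potential: a single number (mV) or a function of
#'   time `f(t_ns) -> mV` defined on `[0, duration]`
#' @param cfg a [sim_config()]
#' @param r_c coupling resistance (GOhm): a single number (0 = uncoupled) or
#'   a function of time
#' @return An object of class `rset_run`: list with
#'   \describe{
#'     \item{spikes}{a `spike_train` (see [bin_spike_counts()])}
#'     \item{events}{data.frame `member`, `time` (ns), `pre_potential` (mV,
#'       potential immediately before reset)}
#'     \item{traces}{if requested, list with `time`, `V` (steps x N matrix)
#'       and `drive` (the frozen driving potential)}
#'     \item{dt, duration, config}{bookkeeping}
#'   }
#' @examples
#' ens <- sample_ensemble(4, heterogeneity_spec(delta = 0), seed = 1)
#' run <- run_rset(ens, input = 120, sim_config(duration = 100, seed = 2))
#' nrow(run$events)
#' @export
run_rset <- function(ensemble, input, cfg, r_c = 0) {
  stopifnot(inherits(ensemble, "rset_ensemble"), inherits(cfg, "sim_config"))
  N <- nrow(ensemble)
  tau <- ensemble$tau
  V_th <- ensemble$V_th
  R <- ensemble$R
  tau_min <- min(tau)
  dt <- if (is.null(cfg$dt)) tau_min / 100 else cfg$dt
  if (dt > tau_min / 50) {
    warning(sprintf(
      "dt = %g ns is coarser than tau_min/50 = %g ns: per-step tunneling %s",
      dt, tau_min / 50, "probabilities may be inaccurate"), call. = FALSE)
  }
  nsteps <- if (cfg$duration == 0) 0L else as.integer(ceiling(cfg$duration / dt))
  kT <- thermal_energy(cfg$temperature)

  t_start <- (seq_len(nsteps) - 1) * dt
  t_end <- seq_len(nsteps) * dt

  ## resolve drive and coupling series once (frozen at step start)
  V_in <- if (is.function(input)) {
    v <- input(t_start)
    if (length(v) == 1L && nsteps > 1L) v <- rep(v, nsteps)
    if (length(v) != nsteps) v <- vapply(t_start, input, numeric(1))
    v
  } else rep(as.numeric(input), nsteps)
  rc_t <- if (is.function(r_c)) {
    v <- r_c(t_start)
    if (length(v) == 1L && nsteps > 1L) v <- rep(v, nsteps)
    if (length(v) != nsteps) v <- vapply(t_start, r_c, numeric(1))
    v
  } else rep(as.numeric(r_c), nsteps)
  if (any(rc_t < 0)) stop("coupling resistance must be non-negative", call. = FALSE)

  decay <- exp(-dt / tau)
  g <- 1 / ensemble$r
  sum_g <- sum(g)
  metropolis <- identical(cfg$rule, "metropolis")

  do_traces <- cfg$record_traces
  stride <- cfg$trace_stride
  n_rec <- if (do_traces) length(seq.int(stride, nsteps, by = stride)) else 0L
  if (do_traces && n_rec > 0) {
    trace_V <- matrix(NA_real_, nrow = n_rec, ncol = N)
    trace_t <- numeric(n_rec)
    trace_drive <- numeric(n_rec)
  }

  ## growable event buffers
  cap <- 1024L
  ev_member <- integer(cap); ev_time <- numeric(cap); ev_pre <- numeric(cap)
  n_ev <- 0L

  max_p <- 0

  with_seed(cfg$seed, {
    Vm <- numeric(N)   # all NP potentials start at zero
    rec <- 0L
    for (k in seq_len(nsteps)) {
      rck <- rc_t[k]
      drive <- if (rck > 0) {
        (V_in[k] / rck + sum(Vm * g)) / (1 / rck + sum_g)
      } else V_in[k]
      Vm <- drive + (Vm - drive) * decay
      dE <- .E_CHARGE * (Vm - V_th)
      if (metropolis) {
        p <- exp(pmin(dE, 0) / kT)
      } else {
        p <- -expm1(-tunneling_rate(dE, R, cfg$temperature) * dt)
        mp <- max(p[dE < 0], 0)
        if (mp > max_p) max_p <- mp
      }
      fire <- stats::runif(N) < p
      if (any(fire)) {
        idx <- which(fire)
        m <- length(idx)
        if (n_ev + m > cap) {
          cap <- max(2L * cap, n_ev + m)
          length(ev_member) <- cap; length(ev_time) <- cap; length(ev_pre) <- cap
        }
        sel <- n_ev + seq_len(m)
        ev_member[sel] <- idx
        ev_time[sel] <- t_end[k]
        ev_pre[sel] <- Vm[idx]
        n_ev <- n_ev + m
        Vm[idx] <- Vm[idx] - 2 * V_th[idx]
      }
      if (do_traces && k %% stride == 0L) {
        rec <- rec + 1L
        trace_V[rec, ] <- Vm
        trace_t[rec] <- t_end[k]
        trace_drive[rec] <- drive
      }
    }
    NULL
  })

  if (!metropolis && max_p > 0.1) {
    warning(sprintf(
      "sub-threshold per-step tunneling probability reached %.3f (> 0.1): dt too coarse",
      max_p), call. = FALSE)
  }

  events <- data.frame(member = ev_member[seq_len(n_ev)],
                       time = ev_time[seq_len(n_ev)],
                       pre_potential = ev_pre[seq_len(n_ev)])
  structure(
    list(spikes = as_spike_train(events, duration = cfg$duration, N = N),
         events = events,
         traces = if (do_traces && n_rec > 0) {
           list(time = trace_t, V = trace_V, drive = trace_drive)
         } else NULL,
         dt = dt, duration = cfg$duration, config = cfg),
    class = "rset_run"
  )
}

#' Spike train container
#'
#' Per-member ordered tunneling-event (spike) times.
#'
#' @param events data.frame with columns `member` and `time` (ns)
#' @param duration covered time window (ns)
#' @param N number of members (defaults to `max(member)`)
#' @return object of class `spike_train`: list with `times` (list of `N`
#'   increasing numeric vectors), `duration`, `N`
#' @export
as_spike_train <- function(events, duration, N = NULL) {
  if (is.null(N)) N <- if (nrow(events)) max(events$member) else 0L
  times <- rep(list(numeric(0)), N)
  if (nrow(events)) {
    sp <- split(events$time, factor(events$member, levels = seq_len(N)))
    times <- lapply(sp, function(x) sort(as.numeric(x)))
  }
  structure(list(times = times, duration = duration, N = as.integer(N)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike train: %d members, %d events over %g ns\n",
              x$N, sum(lengths(x$times)), x$duration))
  invisible(x)
}

#' Per-member spike counts
#' @param spikes a `spike_train`
#' @return integer vector of length `N`
#' @export
spike_counts <- function(spikes) {
  stopifnot(inherits(spikes, "spike_train"))
  lengths(spikes$times)
}

#' Bin ensemble spike counts in time
#'
#' Divides `[0, duration]` into half-open bins `[k*w, (k+1)*w)` of width `w`
#' and counts the total number of spikes of the whole ensemble in each bin.
#' A trailing partial bin (when `duration` is not a multiple of `w`) is
#' retained and flagged; events falling exactly on the final edge are
#' counted in the last bin.
#'
#' @param spikes a `spike_train`
#' @param bin_width bin width `w` in ns (> 0), default 30
#' @return object of class `binned_counts`: list with `counts`, `edges`
#'   (length `nbins + 1`), `centers`, `bin_width`, `partial_last`
#' @export
bin_spike_counts <- function(spikes, bin_width = 30) {
  stopifnot(inherits(spikes, "spike_train"))
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  dur <- spikes$duration
  nbins <- max(1L, as.integer(ceiling(dur / bin_width - 1e-12)))
  t <- unlist(spikes$times, use.names = FALSE)
  idx <- pmin(floor(t / bin_width) + 1L, nbins)
  counts <- tabulate(idx, nbins)
  structure(
    list(counts = counts,
         edges = c((seq_len(nbins) - 1) * bin_width, min(nbins * bin_width, dur)),
         centers = (seq_len(nbins) - 0.5) * bin_width,
         bin_width = bin_width,
         partial_last = abs(dur - nbins * bin_width) > 1e-9),
    class = "binned_counts"
  )
}
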