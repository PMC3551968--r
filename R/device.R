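#' Physical parameters of a single R-SET oscillator
#'
#' An R-SET is a ligand-stabilised metallic nanoparticle (NP) acting as a
#' single-electron transistor -- a capacitance `C` in parallel with a tunnel
#' junction of resistance `R` -- connected in series to a high charging
#' resistance `r`.  Coulomb blockade makes the unit a relaxation oscillator:
#' the NP potential charges towards the applied potential with time constant
#' `tau = r*C` and, once the potential exceeds the threshold
#' `V_th = e/(2C)`, a single electron tunnels and resets the potential by
#' `-2*V_th`.
#'
#' @param C island capacitance in aF (default 1 aF)
#' @param r charging resistance in GOhm (default 10 GOhm)
#' @param R tunnel junction resistance in GOhm (default 0.01 GOhm = 10 MOhm)
#' @return An object of class `rset_params`: a list with fields `C`, `r`,
#'   `R` and the derived threshold potential `V_th` (mV) and charging time
#'   constant `tau` (ns).
#' @details The charging plateau picture assumes `r >> R`; a ratio
#'   `r/R < 10` triggers a warning.  The tunnel resistance should also
#'   exceed the quantum resistance h/(2 e^2) ~ 12.9 kOhm for the
#'   single-electron (orthodox) description to hold; smaller values warn
#'   but are not rejected.
#' @examples
#' p <- rset_params()
#' p$V_th   # ~80.11 mV
#' p$tau    # 10 ns
#' @export
rset_params <- function(C = 1, r = 10, R = 0.01) {
  for (nm in c("C", "r", "R")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single positive number", nm), call. = FALSE)
    }
  }
  if (r / R < 10) {
    warning("charging resistance r is not much larger than tunnel resistance R ",
            "(r/R < 10): the stable-charging-period assumption is degraded",
            call. = FALSE)
  }
  if (R <= .R_QUANTUM) {
    warning("tunnel resistance R does not exceed the quantum resistance ",
            "h/(2e^2) ~ 12.9 kOhm: orthodox tunneling theory may not apply",
            call. = FALSE)
  }
  structure(
    list(C = C, r = r, R = R,
         V_th = threshold_potential(C),
         tau = r * C),
    class = "rset_params"
  )
}

#' @export
print.rset_params <- function(x, ...) {
  cat("R-SET parameters\n")
  cat(sprintf("  C    = %g aF\n", x$C))
  cat(sprintf("  r    = %g GOhm (charging)\n", x$r))
  cat(sprintf("  R    = %g GOhm (tunnel junction)\n", x$R))
  cat(sprintf("  V_th = %.4f mV (= e/2C)\n", x$V_th))
  cat(sprintf("  tau  = %g ns (= r C)\n", x$tau))
  invisible(x)
}

#' Coulomb-blockade threshold potential
#'
#' The NP potential above which single-electron tunneling onto the island
#' becomes energetically favourable: `V_th = e/(2C)`.
#'
#' @param C island capacitance in aF; vectorised
#' @return threshold potential in mV
#' @examples
#' threshold_potential(1)  # ~80.11 mV
#' @export
threshold_potential <- function(C) {
  if (!is.numeric(C) || any(!is.finite(C)) || any(C <= 0)) {
    stop("`C` must be positive (aF)", call. = FALSE)
  }
  .E_CHARGE / (2 * C)
}

#' Deterministic RC charging update
#'
#' Exact solution of the charging equation `dV_i/dt = (V - V_i)/tau` over a
#' step of length `dt`: the NP potential relaxes exponentially towards the
#' applied potential `V`.
#'
#' @param V_i NP potential at the start of the step (mV); vectorised
#' @param V applied (driving) potential (mV)
#' @param tau charging time constant r*C (ns)
#' @param dt step length (ns, >= 0)
#' @return NP potential after `dt` (mV)
#' @examples
#' charge_update(0, 100, 10, 10)  # 100*(1 - exp(-1)) ~ 63.21 mV
#' @export
charge_update <- function(V_i, V, tau, dt) {
  if (any(dt < 0)) stop("`dt` must be non-negative", call. = FALSE)
  if (any(tau <= 0)) stop("`tau` must be positive", call. = FALSE)
  V + (V_i - V) * exp(-dt / tau)
}

#' Electrostatic energy released by a tunneling event
#'
#' Energy gained when one electron tunnels from the grounded electrode onto
#' an island at potential `V_i`: `dE = e * (V_i - V_th)`.  Positive above
#' threshold (favourable), zero exactly at threshold, negative below.
#'
#' @param V_i NP potential (mV); vectorised
#' @param V_th threshold potential (mV)
#' @return energy change in aF.mV^2
#' @export
energy_change <- function(V_i, V_th) {
  .E_CHARGE * (V_i - V_th)
}

#' Orthodox-theory single-electron tunneling rate
#'
#' `Gamma = dE / (e^2 R * (1 - exp(-dE/kT)))`, the standard orthodox-theory
#' rate for a junction of resistance `R` at temperature `T`.  The removable
#' singularity at `dE = 0` is handled by its limit `kT/(e^2 R)`
#' (applied for `|dE/kT| < 1e-6`).
#'
#' @param dE energy change of the transfer (aF.mV^2); vectorised
#' @param R tunnel junction resistance (GOhm)
#' @param temperature temperature (K)
#' @return tunneling rate in 1/ns
#' @examples
#' tunneling_rate(0, 0.01, 5)  # kT/(e^2 R)
#' @export
tunneling_rate <- function(dE, R, temperature) {
  if (any(R <= 0)) stop("`R` must be positive", call. = FALSE)
  kT <- thermal_energy(temperature)
  x <- dE / kT
  denom <- .E_CHARGE^2 * R
  out <- ifelse(abs(x) < 1e-6,
                kT / denom,
                dE / (denom * (1 - exp(-x))))
  ## dE << -kT: exp(-x) overflows to Inf, giving -Inf in the denominator and
  ## a clean 0 rate; map any residual non-finite values to 0 as well.
  out[!is.finite(out)] <- 0
  out
}

#' Post-tunneling potential reset
#'
#' A tunneling event instantaneously lowers the NP potential by twice the
#' threshold potential: `V_i -> V_i - 2*V_th`.
#'
#' @param V_i NP potential immediately before the event (mV); vectorised
#' @param V_th threshold potential (mV)
#' @return NP potential immediately after the event (mV)
#' @export
apply_tunneling <- function(V_i, V_th) {
  V_i - 2 * V_th
}

#' Zero-temperature oscillation period (closed form)
#'
#' In the deterministic limit (tunneling exactly at threshold, zero thermal
#' smearing) the steady-state spike period follows from integrating the
#' charging equation from the reset level `-V_th` up to `+V_th`:
#' `P = tau * log((V + V_th) / (V - V_th))`.
#' Used as an independent oracle for the stochastic engine.
#'
#' @param V constant applied potential (mV); must exceed the threshold
#' @param params an [rset_params()] object
#' @return period in ns
#' @examples
#' deterministic_period(120, rset_params())  # ~16.12 ns
#' @export
deterministic_period <- function(V, params) {
  stopifnot(inherits(params, "rset_params"))
  if (V <= params$V_th) {
    stop("no oscillation: applied potential V must exceed the threshold V_th",
         call. = FALSE)
  }
  params$tau * log((V + params$V_th) / (V - params$V_th))
}

#' First spike time from a zero initial potential
#'
#' Deterministic time for the NP potential to charge from 0 to threshold:
#' `t1 = -tau * log(1 - V_th/V)`.  Shorter than a steady-state period, since
#' the cycle normally restarts from `-V_th`.
#'
#' @inheritParams deterministic_period
#' @return time in ns
#' @export
first_spike_time <- function(V, params) {
  stopifnot(inherits(params, "rset_params"))
  if (V <= params$V_th) {
    stop("no spike: applied potential V must exceed the threshold V_th",
         call. = FALSE)
  }
  -params$tau * log(1 - params$V_th / V)
}

#' Voltages at which a homogeneous ensemble gains another spike per member
#'
#' For identical units observed over a fixed window from a zero initial
#' state, the per-member spike count is a staircase in the applied potential:
#' the k-th spike fits once `first_spike_time(V) + (k-1) * period(V)` drops
#' below the window.  This solves those level-transition voltages in closed
#' form (by root finding); around them the measured counts are thermally
#' smeared.
#'
#' @param window observation window (ns)
#' @param params an [rset_params()] object
#' @param V_max upper end of the voltage range considered (mV)
#' @return increasing vector of transition voltages (mV), one per spike level
#'   reachable below `V_max`
#' @examples
#' stair_boundaries(30, rset_params(), 160)  # ~84, ~113, ~157 mV
#' @export
stair_boundaries <- function(window, params, V_max = 200) {
  stopifnot(inherits(params, "rset_params"))
  time_k <- function(V, k) {
    first_spike_time(V, params) + (k - 1) * deterministic_period(V, params)
  }
  out <- numeric(0)
  lo <- params$V_th * (1 + 1e-9)
  for (k in seq_len(1000)) {
    if (time_k(V_max, k) > window) break
    out <- c(out, stats::uniroot(function(V) time_k(V, k) - window,
                                 lower = lo, upper = V_max,
                                 tol = 1e-9)$root)
  }
  out
}
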