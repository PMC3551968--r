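#' Sinusoidal input-signal specification
#'
#' The analog test signal is a raised sinusoid that starts at its minimum:
#' `V(t) = V_0 + (V_1/2) * (1 - cos(2*pi*t/period))`,
#' so `V_0` is the minimum applied potential, `V_0 + V_1` the maximum, and
#' `V_1/2` the amplitude.
#'
#' @param V_0 minimum applied potential (mV), default 60
#' @param V_1 peak-to-peak swing (mV, >= 0), default 100 (supra-threshold);
#'   18 mV gives the sub-threshold regime for the default ensemble
#' @param period signal period (ns, > 0), default 300
#' @return object of class `sinusoid_spec`
#' @export
sinusoid_spec <- function(V_0 = 60, V_1 = 100, period = 300) {
  if (V_1 < 0) stop("`V_1` must be non-negative", call. = FALSE)
  if (period <= 0) stop("`period` must be positive", call. = FALSE)
  structure(list(V_0 = V_0, V_1 = V_1, period = period),
            class = "sinusoid_spec")
}

#' Evaluate the sinusoidal input signal
#'
#' @param t time in ns (vectorised, >= 0)
#' @param spec a [sinusoid_spec()]
#' @return applied potential in mV
#' @examples
#' s <- sinusoid_spec(60, 100, 300)
#' sinusoid_input(c(0, 150), s)  # 60 (minimum), 160 (maximum)
#' @export
sinusoid_input <- function(t, spec) {
  stopifnot(inherits(spec, "sinusoid_spec"))
  spec$V_0 + spec$V_1 / 2 * (1 - cos(2 * pi * t / spec$period))
}

#' Reconstruct an analog signal from binned ensemble spike counts
#'
#' Drives the ensemble with the sinusoid, divides the processing time into
#' bins (30 ns by default), counts the total spikes of the ensemble per bin,
#' and scores the reconstruction by the Pearson correlation between the
#' binned counts and the input resampled at the bin centers.  If the counts
#' carry no variation (e.g. a homogeneous ensemble driven entirely below
#' threshold), the fidelity is undefined and reported as `NA` with
#' `fidelity_defined = FALSE`.
#'
#' The regime label is `"supra"` when the signal maximum `V_0 + V_1` exceeds
#' the ensemble mean threshold potential, `"sub"` otherwise.
#'
#' @param spec a [sinusoid_spec()]
#' @param ensemble an [sample_ensemble()] object
#' @param cfg a [sim_config()]; its duration should cover at least one
#'   signal period (default duration 600 ns when `cfg` is omitted)
#' @param bin_width bin width in ns, default 30
#' @return object of class `reconstruction_report`: list with
#'   `binned` (data.frame `bin_center`, `count`, `input`), `fidelity`,
#'   `fidelity_defined`, `regime`, `spikes`, `spec`
#' @export
run_signal_experiment <- function(spec, ensemble,
                                  cfg = sim_config(duration = 600),
                                  bin_width = 30) {
  stopifnot(inherits(spec, "sinusoid_spec"),
            inherits(ensemble, "rset_ensemble"),
            inherits(cfg, "sim_config"))
  if (cfg$duration < spec$period) {
    warning("simulation duration is shorter than one signal period",
            call. = FALSE)
  }
  run <- run_rset(ensemble, function(t) sinusoid_input(t, spec), cfg)
  bc <- bin_spike_counts(run$spikes, bin_width)
  input_at_centers <- sinusoid_input(bc$centers, spec)
  defined <- stats::sd(bc$counts) > 0 && stats::sd(input_at_centers) > 0
  fidelity <- if (defined) {
    stats::cor(bc$counts, input_at_centers)
  } else {
    NA_real_
  }
  regime <- if (spec$V_0 + spec$V_1 > mean(ensemble$V_th)) "supra" else "sub"
  structure(
    list(binned = data.frame(bin_center = bc$centers, count = bc$counts,
                             input = input_at_centers),
         fidelity = fidelity, fidelity_defined = defined,
         regime = regime, spikes = run$spikes, spec = spec),
    class = "reconstruction_report"
  )
}

#' @export
print.reconstruction_report <- function(x, ...) {
  cat(sprintf(
    "signal reconstruction (%s-threshold): %d spikes in %d bins, fidelity %s\n",
    x$regime, sum(x$binned$count), nrow(x$binned),
    if (x$fidelity_defined) sprintf("%.3f", x$fidelity) else "undefined"))
  invisible(x)
}

#' Members with the fewest and the most spikes
#'
#' Identifies the ensemble members with the minimum and maximum spike
#' counts; ties are broken by the lowest member index.  In heterogeneous
#' ensembles driven by a supra-threshold signal these tend to be the members
#' with the highest and lowest threshold potential, respectively.
#'
#' @param spikes a `spike_train`
#' @return list with `min` and `max`, each `list(member, count)`
#' @export
min_max_members <- function(spikes) {
  stopifnot(inherits(spikes, "spike_train"))
  if (spikes$N < 1) stop("spike train has no members", call. = FALSE)
  n <- spike_counts(spikes)
  i_min <- unname(which.min(n))
  i_max <- unname(which.max(n))
  n <- unname(n)
  list(min = list(member = i_min, count = n[i_min]),
       max = list(member = i_max, count = n[i_max]))
}
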