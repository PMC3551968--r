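#' Heterogeneity specification for an R-SET ensemble
#'
#' Nanofabrication produces islands whose capacitance and charging resistance
#' scatter around their nominal values.  The scatter is modelled as
#' independent uniform distributions of relative half-width `delta` around
#' the central values: sampled `C` lies in `C_center*(1 +/- delta)` and
#' sampled `r` in `r_center*(1 +/- delta)`.  `delta = 0` gives an ensemble
#' of identical units.  The tunnel resistance is held at its central value
#' unless `vary_R = TRUE`.
#'
#' @param C_center central capacitance (aF), default 1
#' @param r_center central charging resistance (GOhm), default 10
#' @param R_center central tunnel resistance (GOhm), default 0.01
#' @param delta relative half-width in `[0, 1)`, default 0.25 (representative
#'   of experimental threshold-potential nanostructures)
#' @param vary_R also draw the tunnel resistance from a width-`delta` uniform
#'   distribution (exploratory; default `FALSE`)
#' @param family distribution family; only `"uniform"` is implemented
#' @return object of class `heterogeneity_spec`
#' @examples
#' heterogeneity_spec(delta = 0.25)
#' @export
heterogeneity_spec <- function(C_center = 1, r_center = 10, R_center = 0.01,
                               delta = 0.25, vary_R = FALSE,
                               family = "uniform") {
  for (nm in c("C_center", "r_center", "R_center")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single positive number", nm), call. = FALSE)
    }
  }
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0 || delta >= 1) {
    stop("`delta` must lie in [0, 1): wider distributions would allow ",
         "non-physical (non-positive) parameters", call. = FALSE)
  }
  family <- match.arg(family, "uniform")
  structure(
    list(C_center = C_center, r_center = r_center, R_center = R_center,
         delta = delta, vary_R = isTRUE(vary_R), family = family),
    class = "heterogeneity_spec"
  )
}

#' @export
print.heterogeneity_spec <- function(x, ...) {
  cat(sprintf(
    "R-SET heterogeneity: uniform, delta = %g\n  C in [%g, %g] aF, r in [%g, %g] GOhm, R %s %g GOhm\n",
    x$delta,
    x$C_center * (1 - x$delta), x$C_center * (1 + x$delta),
    x$r_center * (1 - x$delta), x$r_center * (1 + x$delta),
    if (x$vary_R) "around" else "fixed at", x$R_center))
  invisible(x)
}

#' Sample an R-SET ensemble
#'
#' Draws `N` independent units from a [heterogeneity_spec()].  Capacitance
#' and charging resistance are sampled independently per member; the tunnel
#' resistance is fixed at its central value unless the spec says otherwise.
#' Member order is stable and the draw is reproducible under a fixed seed.
#'
#' @param N ensemble size (>= 1)
#' @param spec a [heterogeneity_spec()]; default `heterogeneity_spec()`
#' @param seed optional integer seed; `NULL` uses the current RNG stream
#' @return An object of class `rset_ensemble`: a data.frame with one row per
#'   member and columns `member`, `C`, `r`, `R`, `V_th`, `tau`, carrying the
#'   spec and seed as attributes.
#' @examples
#' ens <- sample_ensemble(64, heterogeneity_spec(delta = 0.25), seed = 1)
#' range(ens$C)  # within [0.75, 1.25] aF
#' @export
sample_ensemble <- function(N, spec = heterogeneity_spec(), seed = NULL) {
  stopifnot(inherits(spec, "heterogeneity_spec"))
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N)) {
    stop("`N` must be a positive integer", call. = FALSE)
  }
  N <- as.integer(N)
  d <- spec$delta
  draws <- with_seed(seed, {
    C <- stats::runif(N, spec$C_center * (1 - d), spec$C_center * (1 + d))
    r <- stats::runif(N, spec$r_center * (1 - d), spec$r_center * (1 + d))
    R <- if (spec$vary_R) {
      stats::runif(N, spec$R_center * (1 - d), spec$R_center * (1 + d))
    } else {
      rep(spec$R_center, N)
    }
    list(C = C, r = r, R = R)
  })
  if (d == 0) {
    ## zero-width distributions: exactly the central values
    draws$C <- rep(spec$C_center, N)
    draws$r <- rep(spec$r_center, N)
    if (!spec$vary_R) draws$R <- rep(spec$R_center, N)
  }
  ens <- data.frame(
    member = seq_len(N),
    C = draws$C, r = draws$r, R = draws$R,
    V_th = threshold_potential(draws$C),
    tau = draws$r * draws$C
  )
  attr(ens, "spec") <- spec
  attr(ens, "seed") <- seed
  class(ens) <- c("rset_ensemble", "data.frame")
  ens
}

#' Summary of the threshold-potential spread of an ensemble
#'
#' Per-member threshold potentials, their range, and a histogram, as used to
#' display the threshold diversity of heterogeneous ensembles.
#'
#' @param ensemble an [sample_ensemble()] object
#' @param breaks passed to [graphics::hist()] (computed without plotting)
#' @return list with `min`, `max`, `V_th` (per member, mV) and `histogram`
#'   (a `histogram` object whose counts sum to `N`)
#' @export
threshold_spread <- function(ensemble, breaks = "Sturges") {
  stopifnot(inherits(ensemble, "rset_ensemble"))
  h <- graphics::hist(ensemble$V_th, breaks = breaks, plot = FALSE)
  list(min = min(ensemble$V_th), max = max(ensemble$V_th),
       V_th = ensemble$V_th, histogram = h)
}

#' Mean charging resistance of an ensemble
#' @param ensemble an `rset_ensemble`
#' @return mean of the member charging resistances (GOhm)
#' @keywords internal
mean_charging_resistance <- function(ensemble) {
  mean(ensemble$r)
}

#' Write / read an ensemble as CSV (provenance record)
#'
#' One row per member with columns `member, C, r, R, V_th, tau`.
#'
#' @param ensemble an `rset_ensemble`
#' @param path file path
#' @return `write_ensemble_csv` returns `path` invisibly;
#'   `read_ensemble_csv` returns an `rset_ensemble` (derived columns are
#'   recomputed and checked against the file).
#' @export
write_ensemble_csv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "rset_ensemble"))
  utils::write.csv(as.data.frame(ensemble), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_csv
#' @export
read_ensemble_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("member", "C", "r", "R")
  if (!all(need %in% names(df))) {
    stop("ensemble CSV must have columns member, C, r, R", call. = FALSE)
  }
  ens <- data.frame(member = df$member, C = df$C, r = df$r, R = df$R,
                    V_th = threshold_potential(df$C), tau = df$r * df$C)
  if ("V_th" %in% names(df) &&
      max(abs(df$V_th - ens$V_th)) > 1e-6 * max(ens$V_th)) {
    warning("stored V_th column disagrees with e/(2C); recomputed values used",
            call. = FALSE)
  }
  class(ens) <- c("rset_ensemble", "data.frame")
  ens
}
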