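#' Natural unit system for single-electron device simulation
#'
#' All computation in this package is carried out in a natural unit system
#' chosen so that every quantity of interest is of order one:
#' potential in mV, capacitance in aF, resistance in GOhm, time in ns,
#' charge in aF.mV and energy in aF.mV^2.  The system is consistent:
#' 1 aF x 1 GOhm = 1 ns exactly, and 1 aF.mV^2 = 1e-24 J.
#' Conversions to SI happen only at I/O boundaries.
#'
#' @return A named list with the constants used throughout the package:
#'   \describe{
#'     \item{e}{elementary charge, 160.2176634 aF.mV}
#'     \item{k_B}{Boltzmann constant, 13.80649 aF.mV^2/K}
#'     \item{R_Q}{quantum resistance h/(2 e^2) in GOhm (~1.29e-5 GOhm,
#'       i.e. ~12.9 kOhm)}
#'   }
#' @examples
#' rset_constants()$e / (2 * 1)   # threshold potential of a 1 aF island, mV
#' @export
rset_constants <- function() {
  list(e = .E_CHARGE, k_B = .K_BOLTZ, R_Q = .R_QUANTUM)
}

## elementary charge: 1.602176634e-19 C = 160.2176634 aF.mV
.E_CHARGE <- 160.2176634
## Boltzmann constant: 1.380649e-23 J/K = 13.80649 aF.mV^2/K
.K_BOLTZ <- 13.80649
## quantum resistance h/(2 e^2) = 12.9064 kOhm, expressed in GOhm
.R_QUANTUM <- 6.62607015e-34 / (2 * 1.602176634e-19^2) * 1e-9

#' Thermal energy kT in natural units
#'
#' @param temperature temperature in kelvin (> 0)
#' @return kT in aF.mV^2
#' @examples
#' thermal_energy(5)  # ~69.03 aF.mV^2
#' @export
thermal_energy <- function(temperature) {
  if (!is.numeric(temperature) || any(temperature <= 0)) {
    stop("`temperature` must be positive (kelvin)", call. = FALSE)
  }
  .K_BOLTZ * temperature
}

## Evaluate `code` under a temporary RNG state seeded with `seed`;
## a NULL seed uses (and advances) the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}
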