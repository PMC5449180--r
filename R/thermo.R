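#' Thermodynamic state and physical constants
#'
#' Bundles the temperature with the physical constants used throughout the
#' package: Boltzmann's constant in simulation units (kcal/mol/K), the gas
#' constant and Faraday's constant for the electrophysiology boundary.
#' Internal units are kcal/mol, Angstrom, ns and K; conversion to mV happens
#' only in the GHK functions.
#'
#' @param temperature Absolute temperature in K. The default 303 K matches the
#'   simulated bilayer conditions of the open-state system; pass 274 K for the
#'   electrophysiology analysis.
#' @return An object of class `thermo_state` with fields `temperature`, `kB`
#'   (kcal/mol/K), `kBT` (kcal/mol), `beta` (1/kcal/mol), `R` (J/mol/K) and
#'   `F` (C/mol).
#' @examples
#' th <- thermo_state(303)
#' th$kBT              # ~0.602 kcal/mol
#' thermo_state(274)$temperature
#' @export
thermo_state <- function(temperature = 303) {
  check_scalar(temperature, "temperature", positive = TRUE)
  obj <- list(
    temperature = temperature,
    kB   = 0.0019872,           # kcal/mol/K
    R    = 8.314,               # J/mol/K
    F    = 96485,               # C/mol
    kBT  = 0.0019872 * temperature,
    beta = 1 / (0.0019872 * temperature)
  )
  class(obj) <- "thermo_state"
  obj
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("<thermo_state> T = %g K, kBT = %.5f kcal/mol, RT/F = %.2f mV\n",
              x$temperature, x$kBT, 1000 * x$R * x$temperature / x$F))
  invisible(x)
}

# RT/F in mV (the GHK slope factor).
rt_over_f_mv <- function(thermo) 1000 * thermo$R * thermo$temperature / thermo$F
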