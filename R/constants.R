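#' Physical constants and unit conversions
#'
#' All unit conversions in the package go through this one table. Package-wide
#' conventions: length in nm, time in ns, voltage in mV, current in pA,
#' conductance in nS, energy in units of kT.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{e_C}{elementary charge, 1.602e-19 C}
#'   \item{kB_J}{Boltzmann constant, J/K}
#'   \item{N_A}{Avogadro constant, 1/mol}
#' }
#' @export
pf_constants <- list(
  e_C  = 1.602e-19,
  kB_J = 1.380649e-23,
  N_A  = 6.02214076e23
)

#' Thermal voltage kT/e in mV
#'
#' @param temperature_K temperature in kelvin
#' @return kT/e in millivolts (about 25.7 mV at 298.15 K)
#' @export
thermal_voltage_mV <- function(temperature_K) {
  pf_constants$kB_J * temperature_K / pf_constants$e_C * 1000
}

# ions per nm^3 for a molar concentration
.number_density_nm3 <- function(conc_M) {
  conc_M * pf_constants$N_A * 1e-24
}
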