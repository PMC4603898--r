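# Physical constants.  All energies in the package are in units of kT at
# 298.15 K, all lengths in Angstrom, all charges in elementary charges.

.csc_temperature <- 298.15
.csc_e2_over_4pieps0 <- 14.39964548            # e^2/(4 pi eps0), eV * Angstrom
.csc_kT_eV <- 8.617333262e-5 * .csc_temperature
# e^2/(4 pi eps0 kT): Coulomb prefactor in kT*Angstrom for unit charges in
# vacuum; divide by the relative permittivity for a dielectric medium.
.csc_coulomb_kT <- .csc_e2_over_4pieps0 / .csc_kT_eV
# 1 particle/Angstrom^3 expressed in mol/L
.csc_molar_per_A3 <- 1e27 / 6.02214076e23

#' Bjerrum length
#'
#' Distance at which two unit charges in a uniform dielectric interact with
#' exactly 1 kT (T = 298.15 K).  About 7.0 Angstrom in water (eps = 80).
#'
#' @param eps relative permittivity of the medium.
#' @return Length in Angstrom.
#' @export
#' @examples
#' bjerrum_length(80)
bjerrum_length <- function(eps = 80) {
  stopifnot(is.numeric(eps), eps > 0)
  .csc_coulomb_kT / eps
}

#' Convert a number density to a molar concentration
#'
#' @param rho number density in particles/Angstrom^3.
#' @return Concentration in mol/L.
#' @export
density_to_molar <- function(rho) rho * .csc_molar_per_A3

#' @rdname density_to_molar
#' @param conc concentration in mol/L.
#' @export
molar_to_density <- function(conc) conc / .csc_molar_per_A3
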