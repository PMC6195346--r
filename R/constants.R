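## Physical constants (CODATA 2018). Internal; all public interfaces take
## voltages in mV, concentrations in mM (ions) or nM (ligands), energies in
## kJ/mol, distances in Angstrom.

.GAS_R <- 8.314          # J mol^-1 K^-1
.FARADAY <- 96485        # C mol^-1
.AVOGADRO <- 6.02214076e23
.ECHARGE <- 1.602176634e-19   # C
.EPS0 <- 8.8541878128e-12     # F m^-1
.KBOLTZ <- 1.380649e-23       # J K^-1

#' Thermal energy RT in kJ/mol
#'
#' @param T absolute temperature (K)
#' @return RT in kJ/mol (2.437 kJ/mol at 293.15 K)
#' @export
rt_kj <- function(T = 293.15) {
  stopifnot(is.numeric(T), T > 0)
  .GAS_R * T / 1000
}

#' Coulomb energy prefactor
#'
#' Returns K = N_A q^2 / (4 pi eps0) in kJ * Angstrom / mol, so that the
#' interaction energy of two elementary charges a distance r (Angstrom) apart
#' in a medium of relative permittivity eps_r is K / (eps_r * r) kJ/mol.
#' Evaluates to about 1389.35 kJ*A/mol.
#'
#' @return scalar, kJ*Angstrom/mol
#' @export
coulomb_k <- function() {
  .AVOGADRO * .ECHARGE^2 / (4 * pi * .EPS0) * 1e10 / 1000
}
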