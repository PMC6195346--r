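## Energetics of electrostatic gating: conversion of relative rates into
## activation-energy differences, Coulombic fits of energy against site or
## pore-entrance valence yielding effective dielectric constants,
## binding-energy changes from EC50 shifts, double-mutant cycle coupling and
## a screened-Coulomb axial pore-potential calculator.

#' Activation-energy difference from the innermost-barrier rate
#'
#' Converts the relative rate of crossing the innermost barrier into the
#' difference between the innermost and outermost activation energies,
#' Delta Ea(in - out) = -RT ln(sigma_beta), in kJ/mol.
#'
#' @param sigma_beta relative innermost-barrier crossing rate (> 0)
#' @param T temperature (K)
#' @return energy difference in kJ/mol (vectorized)
#' @export
delta_Ea <- function(sigma_beta, T = 293.15) {
  if (any(!is.finite(sigma_beta)) || any(sigma_beta <= 0))
    stop("`sigma_beta` must be positive", call. = FALSE)
  -rt_kj(T) * log(sigma_beta)
}

#' Coulombic interaction energy of a charged site with a permeating anion
#'
#' Interaction term of the Coulombic potential: the energetic effect of a
#' site of net valence `z_site` on a unit negative test charge a distance
#' `r` away in a uniform medium of relative permittivity `eps_r`:
#' -K z_site / (eps_r r), with K = N_A q^2 / (4 pi eps0) from
#' [coulomb_k()]. A negative site (z_site < 0) raises the anion barrier
#' (positive energy).
#'
#' @param z_site site valence in elementary charges
#' @param eps_r relative permittivity (> 0)
#' @param r distance in Angstrom (> 0)
#' @return energy in kJ/mol (vectorized over `z_site`)
#' @export
coulomb_energy <- function(z_site, eps_r, r) {
  if (!is.numeric(eps_r) || eps_r <= 0) stop("`eps_r` must be > 0",
                                             call. = FALSE)
  if (!is.numeric(r) || r <= 0) stop("`r` must be > 0", call. = FALSE)
  -coulomb_k() * z_site / (eps_r * r)
}

#' Net valence of the calcium-binding site of a construct
#'
#' Bookkeeping constructor for the assumed net charge of the binding site:
#' the sum of the charges of the five acidic site residues (Glu 654, 702,
#' 705, 734, Asp 738; Glu/Asp -1, Gln/Ser 0, Arg +1) plus +2 per bound
#' divalent cation and +3 per bound Gd.
#'
#' @param construct construct tag: one of `"WT"`, `"G644P"`, `"Q649A"`,
#'   `"PQ"` (G644P/E654Q), `"PR"` (G644P/E654R), `"PR2Q"`
#'   (G644P/E654R/E702Q), `"PQ5Q"` (G644P/E654Q/E705Q), `"PR5Q"`
#'   (G644P/E654R/E705Q), `"5Q"` (all five site residues neutralized)
#' @param n_ca,n_mg,n_gd numbers of bound Ca, Mg and Gd ions
#' @return integer valence in elementary charges
#' @export
site_valence <- function(construct = "G644P", n_ca = 0L, n_mg = 0L,
                         n_gd = 0L) {
  residue_sum <- switch(construct,
    WT = , G644P = , Q649A = -5L,
    PQ = , PR = -5L + switch(construct, PQ = 1L, PR = 2L),
    PR2Q = -2L,
    PQ5Q = -3L,
    PR5Q = -2L,
    `5Q` = 0L,
    stop(sprintf("unknown construct tag '%s'", construct), call. = FALSE))
  stopifnot(n_ca >= 0, n_mg >= 0, n_gd >= 0)
  as.integer(residue_sum + 2L * (n_ca + n_mg) + 3L * n_gd)
}

.coulomb_line_fit <- function(x, y, slope_to_eps, bad_sign) {
  if (length(unique(x)) < 2L)
    stop("need >= 2 distinct valences", call. = FALSE)
  fit <- stats::lm(y ~ x)
  slope <- stats::coef(fit)[["x"]]
  flagged <- bad_sign(slope)
  se <- tryCatch(suppressWarnings(
    summary(fit)$coefficients["x", "Std. Error"]),
    error = function(e) NA_real_)
  df <- max(length(x) - 2L, 1L)
  tq <- stats::qt(0.975, df)
  eps_r <- slope_to_eps(slope)
  ## delta method: |d eps/d slope| = eps_r / |slope|
  eps_ci <- tq * se * abs(eps_r / slope)
  list(fit = fit, slope = slope, intercept = stats::coef(fit)[[1L]],
       eps_r = eps_r, eps_ci = eps_ci, flagged = flagged,
       slope_ci = tq * se)
}

#' Coulombic fit of conduction energetics against binding-site valence
#'
#' Fits Delta Ea(in - out) = slope * valence + intercept and interprets the
#' slope Coulombically as -K/(eps_r r) at the fixed structural distance `r`
#' between the binding site and the innermost barrier, returning the
#' effective relative permittivity of the intervening medium. The CI on
#' eps_r is propagated from the slope CI by the delta method.
#'
#' @param valence site valences (elementary charges, >= 2 distinct)
#' @param dEa Delta Ea(in - out) values (kJ/mol)
#' @param r site-to-barrier distance (Angstrom)
#' @return an object of class `coulomb_fit`: `eps_r`, `intercept` (energy at
#'   valence 0), `slope`, `r`, `ci95` (on eps_r), `flagged` (TRUE when the
#'   slope sign is non-physical for an anion barrier), `fit`
#' @export
fit_valence_energy <- function(valence, dEa, r) {
  stopifnot(length(valence) == length(dEa), r > 0)
  res <- .coulomb_line_fit(valence, dEa,
                           slope_to_eps = function(s) -coulomb_k() / (s * r),
                           bad_sign = function(s) s >= 0)
  structure(list(eps_r = res$eps_r, intercept = res$intercept,
                 slope = res$slope, r = r, ci95 = res$eps_ci,
                 flagged = res$flagged, fit = res$fit),
            class = "coulomb_fit")
}

#' Change in apparent ligand-binding free energy from an EC50 shift
#'
#' Delta Delta G_obs = RT ln(EC50 / EC50_bg): negative values mean higher
#' apparent ligand potency in the mutant than in its background construct.
#'
#' @param ec50 mutant EC50 (nM)
#' @param ec50_bg EC50 of the background construct (nM)
#' @param T temperature (K)
#' @return energy in kJ/mol (vectorized)
#' @export
ddg_obs <- function(ec50, ec50_bg, T = 293.15) {
  if (any(ec50 <= 0) || any(ec50_bg <= 0))
    stop("EC50 values must be positive", call. = FALSE)
  rt_kj(T) * log(ec50 / ec50_bg)
}

#' Coulombic fit of binding energetics against pore-entrance valence
#'
#' Fits Delta Delta G_obs = slope * Delta z_pore + intercept where
#' Delta z_pore is the valence change at the intracellular pore entrance
#' relative to wild type (0 for WT, -1 for Lys -> Ser, -2 for Lys -> Glu),
#' and interprets the slope as K zCa/(eps_r r) at the fixed distance `r`
#' between the pore-entrance residue and the binding site.
#'
#' @param d_z_pore pore-entrance valence changes (elementary charges)
#' @param ddg observed binding-energy changes (kJ/mol)
#' @param r residue-to-site distance (Angstrom)
#' @param z_ca ligand valence (2 for Ca)
#' @return a `coulomb_fit`; `flagged` is TRUE when the slope sign is
#'   non-physical (a more negative pore entrance must favor cation binding)
#' @export
fit_pore_charge_energy <- function(d_z_pore, ddg, r, z_ca = 2) {
  stopifnot(length(d_z_pore) == length(ddg), r > 0, z_ca > 0)
  res <- .coulomb_line_fit(d_z_pore, ddg,
                           slope_to_eps = function(s)
                             coulomb_k() * z_ca / (s * r),
                           bad_sign = function(s) s <= 0)
  structure(list(eps_r = res$eps_r, intercept = res$intercept,
                 slope = res$slope, r = r, z_ca = z_ca, ci95 = res$eps_ci,
                 flagged = res$flagged, fit = res$fit),
            class = "coulomb_fit")
}

#' @export
print.coulomb_fit <- function(x, ...) {
  cat(sprintf("Coulombic fit (r = %g A): eps_r = %.4g +/- %.3g, intercept = %.4g kJ/mol%s\n",
              x$r, x$eps_r, x$ci95, x$intercept,
              if (isTRUE(x$flagged)) "  [flagged: non-physical slope sign]"
              else ""))
  invisible(x)
}

#' Double-mutant cycle coupling energy
#'
#' Coupling = (E_AB - E_parent) - (E_A - E_parent) - (E_B - E_parent).
#' Zero coupling means the two mutations contribute additively
#' (independently) on the parent background, as expected for purely
#' Coulombic (superposable) interactions.
#'
#' @param E_parent,E_A,E_B,E_AB energies of the parent, the two single
#'   mutants and the double mutant on a common reference (kJ/mol)
#' @return coupling energy in kJ/mol
#' @export
mutant_cycle_coupling <- function(E_parent, E_A, E_B, E_AB) {
  (E_AB - E_parent) - (E_A - E_parent) - (E_B - E_parent)
}

#' Debye screening length of an electrolyte
#'
#' @param ionic_strength_mM ionic strength in mM (monovalent salt; mM is
#'   numerically mol/m^3)
#' @param eps_r relative permittivity
#' @param T temperature (K)
#' @return Debye length in Angstrom (Inf at zero ionic strength)
#' @export
debye_length <- function(ionic_strength_mM = 150, eps_r = 80, T = 293.15) {
  stopifnot(ionic_strength_mM >= 0, eps_r > 0, T > 0)
  if (ionic_strength_mM == 0) return(Inf)
  lam <- sqrt(.EPS0 * eps_r * .KBOLTZ * T /
                (2 * .AVOGADRO * .ECHARGE^2 * ionic_strength_mM))
  lam * 1e10
}

#' Screened-Coulomb electrostatic potential along the pore axis
#'
#' Deliberately simplified one-dimensional model of the pore's electrostatic
#' profile: point charges on the pore axis in a uniform dielectric with
#' Debye-Hueckel screening,
#' Phi(z) = sum_i K z_i exp(-d_i/lambda_D) / (eps_r d_i) / F, expressed in
#' mV. It is linear in the charges (superposition) and is intended only for
#' ordering and monotonicity comparisons between charge configurations, not
#' for absolute potentials of a membrane-embedded protein.
#'
#' @param charges data frame with columns `z_pos` (axial position, Angstrom)
#'   and `charge` (elementary charges)
#' @param samples axial sample positions (Angstrom), none coincident with a
#'   charge
#' @param eps_r uniform relative permittivity
#' @param ionic_strength_mM mobile monovalent ion concentration for Debye
#'   screening (0 disables screening)
#' @param T temperature (K)
#' @return data frame with columns `z_pos` (Angstrom) and `phi_mV`
#' @export
axial_potential <- function(charges, samples, eps_r = 80,
                            ionic_strength_mM = 150, T = 293.15) {
  stopifnot(eps_r > 0)
  if (is.null(charges) || nrow(as.data.frame(charges)) == 0L)
    return(data.frame(z_pos = as.numeric(samples),
                      phi_mV = rep(0, length(samples))))
  charges <- as.data.frame(charges)
  stopifnot(all(c("z_pos", "charge") %in% names(charges)),
            all(is.finite(charges$z_pos)), all(is.finite(samples)))
  lam <- debye_length(ionic_strength_mM, eps_r, T)
  phi <- vapply(samples, function(zs) {
    d <- abs(zs - charges$z_pos)
    if (any(d == 0))
      stop("sample coincides with a charge position", call. = FALSE)
    sum(coulomb_k() * charges$charge * exp(-d / lam) / (eps_r * d))
  }, 0)
  ## kJ/mol per elementary charge -> mV: * 1e6 / F
  data.frame(z_pos = as.numeric(samples), phi_mV = phi * 1e6 / .FARADAY)
}
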