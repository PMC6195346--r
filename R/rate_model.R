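## Three-barrier Eyring permeation model for anion conduction.
##
## The pore is modelled as n equally spaced Eyring barriers in a linear
## transmembrane field with no deep wells and no saturation. For TMEM16A-like
## analyses n = 3: two large desolvation barriers at the pore entrances
## sandwich a smaller central barrier at the neck. The shape of the I-V
## relation is governed by the zero-voltage rates of crossing the middle
## (sigma_h) and innermost (sigma_beta) barriers relative to the outermost
## barrier; the amplitude factor A absorbs channel count, open probability
## and the absolute outer-barrier rate.

#' Ionic conditions for the permeation model
#'
#' @param ci intracellular (bath, for an inside-out patch) permeant-ion
#'   concentration in mM
#' @param co extracellular (pipette) permeant-ion concentration in mM
#' @param z ion valence (nonzero integer; -1 for Cl-)
#' @param T absolute temperature in K (recordings at 20 C by default)
#' @return an object of class `ion_condition`
#' @export
ion_condition <- function(ci = 150, co = 150, z = -1L, T = 293.15) {
  stopifnot(is.numeric(ci), length(ci) == 1L, is.finite(ci), ci > 0,
            is.numeric(co), length(co) == 1L, is.finite(co), co > 0,
            is.numeric(T), length(T) == 1L, is.finite(T), T > 0)
  if (!is.numeric(z) || length(z) != 1L || z != round(z) || z == 0)
    stop("`z` must be a nonzero integer valence", call. = FALSE)
  structure(list(ci = ci, co = co, z = as.integer(z), T = T),
            class = "ion_condition")
}

#' Parameters of the three-barrier permeation model
#'
#' @param A amplitude factor (> 0); sets the current scale and absorbs the
#'   absolute outer-barrier crossing rate and the proportionality volume
#' @param sigma_h rate of crossing the middle barrier relative to the
#'   outermost barrier at 0 mV (> 0)
#' @param sigma_beta rate of crossing the innermost barrier relative to the
#'   outermost barrier at 0 mV (> 0)
#' @param n number of barriers (integer >= 3; all analyses here use 3)
#' @param condition an [ion_condition()]
#' @return an object of class `permeation_params`
#' @export
permeation_params <- function(A = 1, sigma_h = 1, sigma_beta = 1, n = 3L,
                              condition = ion_condition()) {
  stopifnot(inherits(condition, "ion_condition"))
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A <= 0)
    stop("`A` must be a positive finite number", call. = FALSE)
  if (!is.numeric(sigma_h) || length(sigma_h) != 1L || !is.finite(sigma_h) ||
      sigma_h <= 0)
    stop("`sigma_h` must be positive", call. = FALSE)
  if (!is.numeric(sigma_beta) || length(sigma_beta) != 1L ||
      !is.finite(sigma_beta) || sigma_beta <= 0)
    stop("`sigma_beta` must be positive", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 3)
    stop("`n` must be an integer >= 3", call. = FALSE)
  structure(list(A = A, sigma_h = sigma_h, sigma_beta = sigma_beta,
                 n = as.integer(n), condition = condition),
            class = "permeation_params")
}

#' @export
print.permeation_params <- function(x, ...) {
  cat(sprintf(
    "Permeation model (n = %d barriers): A = %.4g, sigma_h = %.4g, sigma_beta = %.4g\n",
    x$n, x$A, x$sigma_h, x$sigma_beta))
  cat(sprintf("  ci = %g mM, co = %g mM, z = %+d, T = %g K\n",
              x$condition$ci, x$condition$co, x$condition$z, x$condition$T))
  invisible(x)
}

#' Model current at given membrane potentials
#'
#' Evaluates the n-barrier permeation current
#' \deqn{I = zFA e^{u/2n} (c_i - c_o e^{-u}) / D(u)}
#' with \eqn{u = zFV/RT} and denominator
#' \deqn{D(u) = e^{-u(n-1)/n} + \frac{1}{\sigma_h}\,
#'   \frac{1 - e^{-u(n-2)/n}}{e^{u/n} - 1} + \frac{1}{\sigma_\beta}.}
#' Outward current (anion influx at positive V for z = -1) is positive.
#' The current reverses at the Nernst potential (RT/zF) ln(co/ci), is ohmic
#' near 0 mV in symmetric solutions, and for n = 3 with sigma_h = sigma_beta
#' = 1 and ci = co = c reduces exactly to 2 z F A c sinh(zFV/6RT).
#'
#' @param params a [permeation_params()]
#' @param V membrane potential(s) in mV (numeric vector)
#' @return current on the scale set by `A` (same length as `V`)
#' @export
barrier_current <- function(params, V) {
  stopifnot(inherits(params, "permeation_params"))
  if (length(V) == 0L) return(numeric(0))
  if (!is.numeric(V) || any(!is.finite(V)))
    stop("`V` must be finite numeric (mV)", call. = FALSE)
  cnd <- params$condition
  n <- params$n
  u <- cnd$z * .FARADAY * (V / 1000) / (.GAS_R * cnd$T)
  num <- cnd$z * .FARADAY * params$A * exp(u / (2 * n)) *
    (cnd$ci - cnd$co * exp(-u))
  ## middle-barrier geometric-series term; u -> 0 is a removable singularity
  ## with analytic limit (n - 2)
  gs <- ifelse(u == 0, n - 2, (-expm1(-u * (n - 2) / n)) / expm1(u / n))
  den <- exp(-u * (n - 1) / n) + gs / params$sigma_h + 1 / params$sigma_beta
  num / den
}

#' Model I-V curve over a voltage list
#'
#' @param params a [permeation_params()]
#' @param voltages membrane potentials in mV
#' @return data frame with columns `V` (mV) and `I`, in input order
#' @export
iv_curve <- function(params, voltages) {
  data.frame(V = as.numeric(voltages),
             I = barrier_current(params, voltages))
}

#' Rectification index I(-100)/I(+120)
#'
#' Quantifies the asymmetry of an I-V relation as the ratio of the current at
#' -100 mV to that at +120 mV. Both voltages must be present in the curve;
#' no interpolation is performed.
#'
#' @param curve data frame with columns `V` and `I`
#' @param v_neg,v_pos the two voltages defining the index (mV)
#' @return scalar ratio (negative for a curve that reverses between them)
#' @export
rectification_index <- function(curve, v_neg = -100, v_pos = 120) {
  stopifnot(is.data.frame(curve), all(c("V", "I") %in% names(curve)))
  i_neg <- which(abs(curve$V - v_neg) < 1e-9)
  i_pos <- which(abs(curve$V - v_pos) < 1e-9)
  if (length(i_neg) != 1L || length(i_pos) != 1L)
    stop(sprintf("curve must contain exactly one point at %g and at %g mV",
                 v_neg, v_pos), call. = FALSE)
  if (curve$I[i_pos] == 0)
    stop("current at the reference voltage is zero", call. = FALSE)
  curve$I[i_neg] / curve$I[i_pos]
}

#' Relative energy-barrier profile of the conduction path
#'
#' Converts the relative rates into barrier heights relative to the outermost
#' barrier, -RT ln sigma (kJ/mol), at the electrical distances of the three
#' barrier peaks. With n = 3 equally spaced barriers in a linear field the
#' peaks sit at electrical distances 1/6, 1/2 and 5/6 along the
#' extracellular-to-intracellular axis.
#'
#' @param params a [permeation_params()] with n = 3
#' @param render_width Gaussian sigma used only for visualization
#'   (electrical-distance units)
#' @return an object of class `barrier_profile` with fields `positions`,
#'   `rel_heights` (kJ/mol, outer barrier = 0) and `render_width`
#' @export
barrier_profile <- function(params, render_width = 0.08) {
  stopifnot(inherits(params, "permeation_params"))
  if (params$n != 3L)
    stop("barrier_profile is defined for the n = 3 model", call. = FALSE)
  rt <- rt_kj(params$condition$T)
  structure(list(
    positions = c(outer = 1 / 6, middle = 1 / 2, inner = 5 / 6),
    rel_heights = c(outer = 0,
                    middle = -rt * log(params$sigma_h),
                    inner = -rt * log(params$sigma_beta)),
    render_width = render_width), class = "barrier_profile")
}

#' Render a barrier profile as a sum of three Gaussians
#'
#' Visualization helper: the profile is drawn as a sum of three Gaussians
#' whose peak positions and amplitudes indicate barrier locations and
#' relative heights. Each Gaussian's amplitude is `baseline` plus the
#' barrier's relative height, so peak values equal baseline + rel_height up
#' to the (sub-percent at the default width) overlap of neighbours.
#'
#' @param profile a [barrier_profile()]
#' @param grid electrical-distance sample points in \[0, 1\]
#' @param baseline common offset added to every amplitude (kJ/mol)
#' @return data frame with columns `x` (electrical distance) and `energy`
#'   (kJ/mol)
#' @export
render_profile <- function(profile, grid = seq(0, 1, length.out = 201),
                           baseline = 0) {
  stopifnot(inherits(profile, "barrier_profile"))
  if (length(grid) && (any(grid < 0) || any(grid > 1)))
    stop("`grid` must lie within [0, 1]", call. = FALSE)
  w <- profile$render_width
  amps <- baseline + profile$rel_heights
  energy <- rep(0, length(grid))
  for (k in seq_along(profile$positions)) {
    energy <- energy + amps[[k]] * exp(-(grid - profile$positions[[k]])^2 /
                                         (2 * w^2))
  }
  data.frame(x = grid, energy = energy)
}

#' Nernst reversal potential of the model
#'
#' @param condition an [ion_condition()]
#' @return reversal potential in mV, (RT/zF) ln(co/ci)
#' @export
reversal_potential <- function(condition) {
  stopifnot(inherits(condition, "ion_condition"))
  1000 * .GAS_R * condition$T / (condition$z * .FARADAY) *
    log(condition$co / condition$ci)
}
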