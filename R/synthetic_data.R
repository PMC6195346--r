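## Synthetic inside-out-patch data generator. Emulates the statistical
## structure the analysis chain assumes: three-barrier model currents whose
## sigma parameters are Hill-modulated by the intracellular ligand, a
## voltage-dependent EC50 (ligand bound within the field), irreversible
## multiplicative rundown along the voltage-step train, ohmic leak, additive
## current noise, and bracketing zero-ligand recordings. Every dataset
## carries its generating truth for recovery and calibration tests; the
## truth is never consumed by the pipeline under test.

#' Ground-truth parameter block for a construct
#'
#' Default per-construct truths. Printed dose-response anchors (inner
#' barrier EC50 60 nM / h 2.1 and central barrier EC50 170 nM / h 1.7 at a
#' +80 mV pre-pulse for the reference constitutively active construct) are
#' taken as the generator's defaults; sigma floors/ceilings are invented
#' defaults chosen to reproduce the qualitative I-V shapes (strong outward
#' rectification at zero ligand, pseudo-linear at saturation). Pore-entrance
#' mutant EC50s are derived self-consistently from the pore-charge Coulombic
#' truths so that forward-generated datasets are exactly linear in valence.
#'
#' @param construct construct tag (see [site_valence()]; plus `"K588S"`,
#'   `"K645S"`, `"K588E"`, `"K645E"`)
#' @param ligand `"Ca"` or `"Mg"` (Mg acts as a single-site, low-affinity,
#'   partial-efficacy agonist of the reference construct)
#' @return list of truth parameters (`A`, sigma bounds, EC50s at the
#'   reference pre-pulse voltage, Hill coefficients, `zf_product`, flags)
#' @export
construct_truth <- function(construct = "G644P", ligand = c("Ca", "Mg")) {
  ligand <- match.arg(ligand)
  base <- list(A = 4e-5, ref_V = 80, zf_product = 0.5, one_site = FALSE,
               biphasic = FALSE, basal = TRUE)
  tr <- switch(construct,
    G644P = list(sigma_beta = c(min = 0.05, max = 1.0),
                 sigma_h = c(min = 0.2, max = 1.0),
                 ec50_beta = 60, h_beta = 2.1,
                 ec50_h = 170, h_h = 1.7),
    Q649A = list(sigma_beta = c(min = 0.05, max = 1.0),
                 sigma_h = c(min = 0.2, max = 1.0),
                 ec50_beta = 80, h_beta = 2.0,
                 ec50_h = 200, h_h = 1.7),
    WT = list(sigma_beta = c(min = 1, max = 1),
              sigma_h = c(min = 1, max = 1),
              ec50_beta = 300, h_beta = 2.0, ec50_h = 300, h_h = 2.0,
              basal = FALSE),
    PQ = list(sigma_beta = c(min = 0.03, max = 0.25),
              sigma_h = c(min = 0.15, max = 0.5),
              ec50_beta = 900, h_beta = 1, ec50_h = 900, h_h = 1,
              one_site = TRUE, biphasic = TRUE),
    PR = list(sigma_beta = c(min = 0.08, max = 0.45),
              sigma_h = c(min = 0.2, max = 0.6),
              ec50_beta = 700, h_beta = 1, ec50_h = 700, h_h = 1,
              one_site = TRUE, biphasic = TRUE),
    PR2Q = list(sigma_beta = c(min = 0.2, max = 0.7),
                sigma_h = c(min = 0.3, max = 0.8),
                ec50_beta = 2000, h_beta = 1, ec50_h = 2000, h_h = 1,
                one_site = TRUE),
    PQ5Q = list(sigma_beta = c(min = 0.08, max = 0.45),
                sigma_h = c(min = 0.2, max = 0.6),
                ec50_beta = 1200, h_beta = 1, ec50_h = 1200, h_h = 1,
                one_site = TRUE, biphasic = TRUE),
    PR5Q = list(sigma_beta = c(min = 0.2, max = 0.7),
                sigma_h = c(min = 0.3, max = 0.8),
                ec50_beta = 900, h_beta = 1, ec50_h = 900, h_h = 1,
                one_site = TRUE, biphasic = TRUE),
    K588S = .pore_mutant_truth("Lys588", -1L, bg_ec50 = 300),
    K645S = .pore_mutant_truth("Lys645", -1L, bg_ec50 = 300),
    K588E = .pore_mutant_truth("Lys588", -2L, bg_ec50 = 3000),
    K645E = .pore_mutant_truth("Lys645", -2L, bg_ec50 = 3000),
    stop(sprintf("unknown construct tag '%s'", construct), call. = FALSE))
  tr <- utils::modifyList(base, tr)
  if (ligand == "Mg") {
    ## single Mg occupies the site: one-site isotherm, intermediate ceiling
    tr$one_site <- TRUE
    tr$sigma_beta["max"] <- 0.5
    tr$sigma_h["max"] <- 0.6
    tr$ec50_beta <- tr$ec50_h <- 1e5
    tr$h_beta <- tr$h_h <- 1
  }
  tr$construct <- construct
  tr$ligand <- ligand
  tr
}

## EC50 of a pore-entrance charge mutant derived from the pore-charge
## Coulombic truth (exact linearity of ddG in the valence change)
.pore_mutant_truth <- function(position, d_z, bg_ec50) {
  pc <- .pore_charge_truth(position)
  ddg <- coulomb_k() * d_z * pc$z_ca / (pc$eps_r * pc$r)
  list(sigma_beta = c(min = 1, max = 1), sigma_h = c(min = 1, max = 1),
       ec50_beta = bg_ec50 * exp(ddg / rt_kj()),
       h_beta = 2, ec50_h = bg_ec50 * exp(ddg / rt_kj()), h_h = 2,
       basal = FALSE)
}

.pore_charge_truth <- function(position = c("Lys645", "Lys588")) {
  position <- match.arg(position)
  if (position == "Lys645") list(eps_r = 71.2, r = 10.6, z_ca = 2)
  else list(eps_r = 131.9, r = 11.9, z_ca = 2)
}

#' Generator configuration
#'
#' @param construct construct tag (see [construct_truth()])
#' @param ligand ligand species (`"Ca"` or `"Mg"`)
#' @param truth truth block, by default [construct_truth()] for the
#'   construct
#' @param voltages test voltage steps in mV (applied in the given order,
#'   low to high, to minimize the impact of rundown on the inward currents)
#' @param prepulse_mV conditioning pre-pulse voltage (mV)
#' @param conc_nM ligand concentration series (nM, > 0)
#' @param n_patches patches per condition
#' @param noise list: `current_sd` (additive current noise as a fraction of
#'   the saturating current at +120 mV; default 0.02), `rundown`
#'   (irreversible fractional decay over one voltage-step train; default
#'   0.12, matching the 10-15% seen experimentally), `leak_nS` (ohmic leak
#'   conductance of a healthy patch), `leaky_rate` (fraction of patches
#'   injected with a large leak), `leaky_leak_nS` (their leak conductance)
#' @param seed integer seed; identical config + seed gives identical output
#' @return a `generator_config` list
#' @export
generator_config <- function(construct = "G644P", ligand = "Ca",
                             truth = construct_truth(construct, ligand),
                             voltages = seq(-100, 120, by = 20),
                             prepulse_mV = 80,
                             conc_nM = c(10, 30, 100, 300, 1000, 10000),
                             n_patches = 5L,
                             noise = list(), seed = 1L) {
  noise_def <- list(current_sd = 0.02, rundown = 0.12, leak_nS = 0,
                    leaky_rate = 0, leaky_leak_nS = 2)
  unknown <- setdiff(names(noise), names(noise_def))
  if (length(unknown))
    stop("unknown noise field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  noise <- utils::modifyList(noise_def, noise)
  stopifnot(all(conc_nM > 0), noise$rundown >= 0, noise$rundown < 1,
            noise$current_sd >= 0, noise$leaky_rate >= 0,
            noise$leaky_rate < 1, n_patches >= 1L)
  structure(list(construct = construct, ligand = ligand, truth = truth,
                 voltages = as.numeric(voltages),
                 prepulse_mV = prepulse_mV, conc_nM = as.numeric(conc_nM),
                 n_patches = as.integer(n_patches), noise = noise,
                 seed = as.integer(seed)), class = "generator_config")
}

.substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + index * 7919) %% 2147483629)
}

## sigma value at a ligand concentration and pre-pulse voltage; the EC50
## shifts with the pre-pulse voltage because the ligand binds within the
## transmembrane field
.truth_sigma <- function(truth, which = c("sigma_beta", "sigma_h"), conc,
                         prepulse_mV, T = 293.15) {
  which <- match.arg(which)
  b <- truth[[which]]
  ec50_ref <- if (which == "sigma_beta") truth$ec50_beta else truth$ec50_h
  h <- if (which == "sigma_beta") truth$h_beta else truth$h_h
  dv <- (prepulse_mV - truth$ref_V) / 1000
  log_ec50 <- log10(ec50_ref) -
    truth$zf_product * dv * .FARADAY / (log(10) * .GAS_R * T)
  ec50 <- 10^log_ec50
  .hill_response(conc, ec50, h, b[["min"]], b[["max"]])
}

#' Generate the sweep table of one synthetic patch
#'
#' Produces instantaneous I-V trains at each ligand concentration, each
#' bracketed by zero-ligand trains (before and after), in the documented
#' sweep-table format. Within a train the voltage steps run low to high and
#' the current scale decays irreversibly (geometric per-step rundown);
#' pre-pulse currents carry the same decay, which is what the pre-pulse
#' normalization exploits. Ohmic leak and additive Gaussian noise are
#' superimposed; a patch may be injected as "leaky" with probability
#' `noise$leaky_rate`.
#'
#' @param config a [generator_config()]
#' @param patch_index positive integer; distinct indices use distinct
#'   random substreams
#' @return list with `sweeps` (data frame in [read_sweeps()] format) and
#'   `truth` (per-condition latent parameters, leak, leaky flag, rundown)
#' @export
generate_patch <- function(config, patch_index = 1L) {
  stopifnot(inherits(config, "generator_config"), patch_index >= 1L)
  set.seed(.substream_seed(config$seed, patch_index))
  tr <- config$truth
  ns <- config$noise
  cond <- ion_condition()
  is_leaky <- stats::runif(1) < ns$leaky_rate
  leak <- if (is_leaky) ns$leaky_leak_nS else ns$leak_nS
  ## noise scale: fraction of the saturating current at +120 mV
  p_sat <- permeation_params(A = tr$A, sigma_h = tr$sigma_h[["max"]],
                             sigma_beta = tr$sigma_beta[["max"]],
                             condition = cond)
  i_scale <- abs(barrier_current(p_sat, 120))
  sd_pA <- ns$current_sd * i_scale
  nv <- length(config$voltages)
  step_decay <- if (nv > 1L) (1 - ns$rundown)^(1 / (nv - 1L)) else 1
  rd <- 1
  patch_id <- sprintf("patch%03d", patch_index)
  rows <- list()
  truth_cond <- list()
  epoch <- 0L
  run_train <- function(conc, epoch, rd) {
    sb <- if (conc > 0)
      .truth_sigma(tr, "sigma_beta", conc, config$prepulse_mV, cond$T)
    else tr$sigma_beta[["min"]]
    sh <- if (conc > 0)
      .truth_sigma(tr, "sigma_h", conc, config$prepulse_mV, cond$T)
    else tr$sigma_h[["min"]]
    p <- permeation_params(A = tr$A, sigma_h = sh, sigma_beta = sb,
                           condition = cond)
    pre <- barrier_current(p, config$prepulse_mV)
    out <- vector("list", nv)
    for (s in seq_len(nv)) {
      v <- config$voltages[s]
      ## pre-pulse amplitude is a time-average of the steady current, so its
      ## noise is well below the instantaneous per-point noise
      i_pre <- pre * rd + leak * config$prepulse_mV +
        stats::rnorm(1, 0, sd_pA / 5)
      i_test <- barrier_current(p, v) * rd + leak * v +
        stats::rnorm(1, 0, sd_pA)
      out[[s]] <- data.frame(patch_id = patch_id, epoch = epoch,
                             ligand = if (conc > 0) config$ligand else "none",
                             conc_nM = conc,
                             prepulse_mV = config$prepulse_mV,
                             prepulse_pA = i_pre, V_mV = v, I_pA = i_test)
      rd <- rd * step_decay
    }
    list(rows = do.call(rbind, out), rd = rd,
         truth = list(conc_nM = conc, sigma_beta = sb, sigma_h = sh,
                      A = tr$A))
  }
  for (conc in config$conc_nM) {
    for (cc in c(0, conc)) {
      res <- run_train(cc, epoch, rd)
      rows[[length(rows) + 1L]] <- res$rows
      truth_cond[[length(truth_cond) + 1L]] <-
        c(res$truth, list(epoch = epoch))
      rd <- res$rd
      epoch <- epoch + 1L
    }
  }
  res <- run_train(0, epoch, rd)   # trailing zero-ligand bracket
  rows[[length(rows) + 1L]] <- res$rows
  truth_cond[[length(truth_cond) + 1L]] <- c(res$truth, list(epoch = epoch))
  list(sweeps = do.call(rbind, rows),
       truth = list(construct = config$construct, patch_id = patch_id,
                    is_leaky = is_leaky, leak_nS = leak,
                    rundown = ns$rundown, A = tr$A,
                    conditions = truth_cond))
}

#' Generate a cohort of synthetic patches
#'
#' @param config a [generator_config()]
#' @return list with `sweeps` (all patches row-bound) and `truths` (one
#'   truth record per patch)
#' @export
generate_cohort <- function(config) {
  out <- lapply(seq_len(config$n_patches),
                function(i) generate_patch(config, i))
  list(sweeps = do.call(rbind, lapply(out, `[[`, "sweeps")),
       truths = lapply(out, `[[`, "truth"))
}

#' Generate a steady-state dose-response family
#'
#' Tabulates the truth sigma values and a normalized steady-state response
#' across the concentration series at the configured pre-pulse voltage,
#' optionally with Gaussian noise (sd = `noise$current_sd` on each value)
#' and, for constructs flagged biphasic, a secondary low-affinity decay of
#' the innermost-barrier rate at high concentrations (interior maximum).
#'
#' @param config a [generator_config()]
#' @return data frame (`conc_nM`, `sigma_beta`, `sigma_h`, `response`) with
#'   attribute `truth`
#' @export
generate_dose_response_family <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(.substream_seed(config$seed, 0L))
  tr <- config$truth
  conc <- config$conc_nM
  sb <- .truth_sigma(tr, "sigma_beta", conc, config$prepulse_mV)
  sh <- .truth_sigma(tr, "sigma_h", conc, config$prepulse_mV)
  decay <- rep(0, length(conc))
  if (isTRUE(tr$biphasic)) {
    ## secondary low-affinity decay three decades above the primary site,
    ## as in the binding-site mutants that show it
    amp <- 0.3 * diff(range(tr$sigma_beta))
    decay <- amp * .hill_response(conc, 1000 * tr$ec50_beta, 1, 0, 1)
  }
  sb_obs <- sb - decay
  resp <- .hill_response(conc, tr$ec50_beta, tr$h_beta, 0, 1)
  sd <- config$noise$current_sd
  if (sd > 0) {
    sb_obs <- sb_obs * (1 + stats::rnorm(length(conc), 0, sd))
    sh <- sh * (1 + stats::rnorm(length(conc), 0, sd))
    resp <- resp + stats::rnorm(length(conc), 0, sd)
  }
  out <- data.frame(conc_nM = conc, sigma_beta = sb_obs, sigma_h = sh,
                    response = resp)
  attr(out, "truth") <- list(construct = config$construct,
                             ligand = config$ligand,
                             ec50_beta = tr$ec50_beta, h_beta = tr$h_beta,
                             ec50_h = tr$ec50_h, h_h = tr$h_h,
                             sigma_beta = tr$sigma_beta,
                             sigma_h = tr$sigma_h,
                             biphasic = isTRUE(tr$biphasic))
  out
}

#' Forward-generate valence-energy and pore-charge datasets
#'
#' Evaluates the Coulombic forward model at the construct valences with the
#' module's default dielectric truths and adds optional Gaussian noise:
#' \itemize{
#' \item `"divalent-occupancy"`: conduction energetics of the reference
#'   construct at binding-site occupancies apo / one Mg / two Ca (valences
#'   -5, -3, -1; eps_r truth 64.8, r = 13.6 A);
#' \item `"one-ca-mutants"`: binding-site mutant series with one Ca bound
#'   (eps_r truth 96.7, r = 13.6 A);
#' \item `"zero-ca-mutants"`: the same mutants, vacant site (eps_r truth
#'   162.7, r = 13.6 A);
#' \item `"pore-charge"`: binding-energy changes against the pore-entrance
#'   valence change 0/-1/-2 at `position` (eps_r truth 71.2 at r = 10.6 A
#'   for Lys645, 131.9 at r = 11.9 A for Lys588; zCa = 2).
#' }
#'
#' @param series dataset tag (above)
#' @param position pore-entrance residue for the `"pore-charge"` series
#' @param noise_sd Gaussian noise sd on the energies (kJ/mol; 0 = noiseless)
#' @param seed integer seed (used only when `noise_sd > 0`)
#' @return data frame of labelled points (`valence`/`d_z_pore` and
#'   `dEa`/`ddg`) with attribute `truth` (eps_r, r, intercept, ...)
#' @export
generate_valence_dataset <- function(series = c("divalent-occupancy",
                                                "one-ca-mutants",
                                                "zero-ca-mutants",
                                                "pore-charge"),
                                     position = "Lys645", noise_sd = 0,
                                     seed = 1L) {
  series <- match.arg(series)
  set.seed(.substream_seed(seed, 99L))
  muts <- c("PQ", "PR", "PR2Q", "PQ5Q", "PR5Q")
  if (series == "pore-charge") {
    pc <- .pore_charge_truth(position)
    d_z <- c(WT = 0L, KtoS = -1L, KtoE = -2L)
    ddg <- coulomb_k() * d_z * pc$z_ca / (pc$eps_r * pc$r)
    if (noise_sd > 0) ddg <- ddg + stats::rnorm(length(ddg), 0, noise_sd)
    out <- data.frame(label = names(d_z), d_z_pore = as.integer(d_z),
                      ddg = as.numeric(ddg))
    attr(out, "truth") <- c(pc, list(intercept = 0, series = series,
                                     position = position))
    return(out)
  }
  spec <- switch(series,
    `divalent-occupancy` = list(
      labels = c("apo", "one Mg", "two Ca"),
      valence = c(site_valence("G644P"), site_valence("G644P", n_mg = 1),
                  site_valence("G644P", n_ca = 2)),
      eps_r = 64.8, r = 13.6,
      intercept = delta_Ea(0.05) - coulomb_energy(site_valence("G644P"),
                                                  64.8, 13.6)),
    `one-ca-mutants` = list(
      labels = muts,
      valence = vapply(muts, site_valence, 0L, n_ca = 1),
      eps_r = 96.7, r = 13.6, intercept = 1.5),
    `zero-ca-mutants` = list(
      labels = muts,
      valence = vapply(muts, site_valence, 0L),
      eps_r = 162.7, r = 13.6, intercept = 1.5))
  if (length(unique(spec$valence)) < 2L)
    stop("degenerate valence series", call. = FALSE)
  dEa <- spec$intercept + coulomb_energy(spec$valence, spec$eps_r, spec$r)
  if (noise_sd > 0) dEa <- dEa + stats::rnorm(length(dEa), 0, noise_sd)
  out <- data.frame(label = spec$labels, valence = as.integer(spec$valence),
                    dEa = as.numeric(dEa))
  attr(out, "truth") <- list(eps_r = spec$eps_r, r = spec$r,
                             intercept = spec$intercept, series = series)
  out
}
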