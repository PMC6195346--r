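## Hill-equation analysis of ligand modulation: steady-state dose-response
## fits, Ca/Mg dependence of the fitted barrier-crossing rates, voltage
## dependence of EC50, rundown-corrected concentration-response construction
## and the exclusion rule for low-affinity decay phases.

.hill_response <- function(conc, ec50, h, floor, ceiling) {
  ## evaluated in log10-concentration space; conc = 0 maps to the floor
  floor + (ceiling - floor) / (1 + 10^((log10(ec50) - log10(conc)) * h))
}

.hill_resid <- function(theta, conc, resp, fix_h, fix_bounds) {
  ec50 <- exp(theta[1L])
  h <- if (fix_h) 1 else exp(theta[2L])
  if (fix_bounds) {
    fl <- 0; ce <- 1
  } else {
    fl <- theta[if (fix_h) 2L else 3L]
    ce <- theta[if (fix_h) 3L else 4L]
  }
  .hill_response(conc, ec50, h, fl, ce) - resp
}

#' Fit the Hill equation to a dose-response series
#'
#' Least-squares fit of
#' \deqn{y = floor + (ceiling - floor) / (1 + 10^{(\log EC_{50} - \log c) h})}
#' in log10-concentration space. EC50 and the Hill coefficient are fitted on
#' the log scale (positivity); zero concentrations are handled exactly (they
#' pin the floor). For a single binding site set `fix_h_to_one = TRUE`.
#'
#' @param conc ligand concentrations (nM; zeros allowed)
#' @param response responses (raw or normalized)
#' @param fix_h_to_one constrain the Hill coefficient to 1
#' @param fix_bounds fix floor = 0 and ceiling = 1 (for pre-normalized
#'   I/Imax data) instead of fitting them
#' @return an object of class `hill_fit`: `ec50` (nM), `h`, `floor`,
#'   `ceiling`, `ci95` (half-widths), `conf.int` (ec50 and h, log-scale
#'   asymptotic bounds), `rss`, `df`, `unidentifiable`
#' @export
fit_hill <- function(conc, response, fix_h_to_one = FALSE,
                     fix_bounds = FALSE) {
  stopifnot(length(conc) == length(response), all(conc >= 0),
            all(is.finite(response)))
  if (length(conc) < 4L || sum(conc > 0) < 3L)
    stop("need at least 4 points (>= 3 at nonzero concentration)",
         call. = FALSE)
  span <- diff(range(response))
  if (span <= 0.1 * max(abs(response), .Machine$double.eps)) {
    return(structure(list(ec50 = NA_real_, h = NA_real_,
                          floor = min(response), ceiling = max(response),
                          ci95 = NULL, conf.int = NULL, rss = NA_real_,
                          df = NA_integer_, unidentifiable = TRUE),
                     class = "hill_fit"))
  }
  ## start EC50 at the concentration where the response crosses mid-range
  pos <- conc > 0
  mid <- (min(response) + max(response)) / 2
  ec0 <- exp(stats::approx(response[pos][order(conc[pos])],
                           log(conc[pos][order(conc[pos])]),
                           xout = mid, ties = mean, rule = 2)$y)
  if (!is.finite(ec0) || ec0 <= 0) ec0 <- stats::median(conc[pos])
  th0 <- log(ec0)
  if (!fix_h_to_one) th0 <- c(th0, log(1))
  if (!fix_bounds) th0 <- c(th0, min(response), max(response))
  fit <- minpack.lm::nls.lm(par = th0, fn = .hill_resid, conc = conc,
                            resp = response, fix_h = fix_h_to_one,
                            fix_bounds = fix_bounds,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  npar <- length(th0)
  df <- length(conc) - npar
  theta <- fit$par
  ec50 <- exp(theta[1L])
  h <- if (fix_h_to_one) 1 else exp(theta[2L])
  if (fix_bounds) {
    fl <- 0; ce <- 1
  } else {
    fl <- theta[npar - 1L]; ce <- theta[npar]
  }
  s2 <- fit$deviance / max(df, 1L)
  cov <- tryCatch(s2 * solve(fit$hessian), error = function(e) NULL)
  se <- if (is.null(cov)) rep(NA_real_, npar) else sqrt(pmax(diag(cov), 0))
  tq <- stats::qt(0.975, max(df, 1L))
  ci <- rbind(ec50 = ec50 * exp(c(-1, 1) * tq * se[1L]),
              h = if (fix_h_to_one) c(1, 1) else
                h * exp(c(-1, 1) * tq * se[2L]))
  colnames(ci) <- c("lower", "upper")
  half <- c(ec50 = tq * se[1L] * ec50,
            h = if (fix_h_to_one) 0 else tq * se[2L] * h,
            floor = if (fix_bounds) 0 else tq * se[npar - 1L],
            ceiling = if (fix_bounds) 0 else tq * se[npar])
  structure(list(ec50 = ec50, h = h, floor = fl, ceiling = ce,
                 ci95 = half, conf.int = ci, rss = fit$deviance, df = df,
                 unidentifiable = FALSE),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (isTRUE(x$unidentifiable)) {
    cat("Hill fit: unidentifiable (responses do not span the transition)\n")
    return(invisible(x))
  }
  cat(sprintf("Hill fit: EC50 = %.4g nM, h = %.3g, floor = %.4g, ceiling = %.4g\n",
              x$ec50, x$h, x$floor, x$ceiling))
  invisible(x)
}

#' Concentration series of a fitted barrier-crossing rate
#'
#' @param conc_nM ligand concentrations (strictly increasing, nM)
#' @param sigma fitted relative rates at each concentration
#' @param param which rate the series tracks (`"sigma_beta"` or `"sigma_h"`)
#' @param ligand ligand tag
#' @param voltage_mV pre-pulse voltage the rates refer to
#' @param ci95 optional per-point confidence half-widths
#' @return an object of class `sigma_series` (data frame with columns
#'   `conc_nM`, `sigma`, `included`)
#' @export
sigma_series <- function(conc_nM, sigma, param = c("sigma_beta", "sigma_h"),
                         ligand = "Ca", voltage_mV = 80, ci95 = NULL) {
  stopifnot(length(conc_nM) == length(sigma), !is.unsorted(conc_nM,
                                                           strictly = TRUE))
  param <- match.arg(param)
  out <- data.frame(conc_nM = conc_nM, sigma = sigma, included = TRUE)
  if (!is.null(ci95)) out$ci95 <- ci95
  structure(out, class = c("sigma_series", "data.frame"),
            param = param, ligand = ligand, voltage_mV = voltage_mV)
}

#' Mask the low-affinity decay phase of a sigma series
#'
#' Some binding-site mutants show a secondary low-affinity decay of the
#' innermost-barrier rate at high ligand concentrations; only the
#' high-affinity rising phase is analyzed. The rule keeps every point up to
#' and including the series maximum and masks points beyond it whose value
#' falls more than `tol` below the maximum. It is idempotent and never masks
#' the maximum itself.
#'
#' @param series a [sigma_series()]
#' @param tol fractional drop below the maximum that triggers masking
#'   (default 0.05)
#' @return the series with its `included` mask updated
#' @export
exclude_low_affinity_phase <- function(series, tol = 0.05) {
  stopifnot(inherits(series, "sigma_series"), nrow(series) >= 3L,
            tol >= 0)
  m <- which.max(series$sigma)
  smax <- series$sigma[m]
  mask <- rep(TRUE, nrow(series))
  after <- seq_len(nrow(series)) > m
  mask[after & series$sigma < (1 - tol) * smax] <- FALSE
  series$included <- series$included & mask
  series
}

#' Hill fit of a sigma series
#'
#' Fits the ligand dependence of a relative barrier-crossing rate,
#' sigma(c) = sigma_min + (sigma_max - sigma_min) Hill(c), returning the
#' floor and ceiling as sigma_min and sigma_max. The low-affinity exclusion
#' rule is applied first unless already applied.
#'
#' @param series a [sigma_series()]
#' @param fix_h_to_one constrain h to 1 (single-site ligands)
#' @param exclude apply [exclude_low_affinity_phase()] before fitting
#' @param tol exclusion tolerance
#' @return a `hill_fit` (floor = sigma_min, ceiling = sigma_max)
#' @export
fit_sigma_series <- function(series, fix_h_to_one = FALSE, exclude = TRUE,
                             tol = 0.05) {
  stopifnot(inherits(series, "sigma_series"))
  if (exclude) series <- exclude_low_affinity_phase(series, tol = tol)
  keep <- series$included
  if (sum(keep) < 4L)
    stop("fewer than 4 included points in the sigma series", call. = FALSE)
  fit_hill(series$conc_nM[keep], series$sigma[keep],
           fix_h_to_one = fix_h_to_one)
}

#' Voltage dependence of EC50
#'
#' Fits log10 EC50 = log10 EC50(0) - (1/2.303) zCa fV V F / RT, a line in V
#' whose slope yields the product of the ligand valence and the electrical
#' distance fV of its binding site within the transmembrane field.
#'
#' @param V_mV membrane potentials (mV), >= 3 values
#' @param ec50_nM EC50 at each potential (nM)
#' @param z_ca ligand valence (default 2 for Ca)
#' @param T temperature (K)
#' @return an object of class `ec50_voltage_fit`: `log_ec50_0` (log10 nM at
#'   0 mV), `ec50_0`, `zf_product` (zCa * fV), `f_v`, `ci95`, `fit` (the
#'   underlying `lm`)
#' @export
fit_ec50_voltage <- function(V_mV, ec50_nM, z_ca = 2, T = 293.15) {
  stopifnot(length(V_mV) == length(ec50_nM), all(ec50_nM > 0))
  if (length(V_mV) < 3L) stop("need >= 3 voltages", call. = FALSE)
  y <- log10(ec50_nM)
  Vv <- V_mV / 1000
  fit <- stats::lm(y ~ Vv)
  slope <- stats::coef(fit)[["Vv"]]
  ## slope = -(1/ln10) zCa fV F/RT  =>  zCa fV = -slope ln10 RT/F
  zf <- -slope * log(10) * .GAS_R * T / .FARADAY
  se <- tryCatch(suppressWarnings(
    summary(fit)$coefficients[, "Std. Error"]),
    error = function(e) rep(NA_real_, 2L))
  tq <- stats::qt(0.975, max(length(V_mV) - 2L, 1L))
  ci <- c(log_ec50_0 = tq * se[[1L]],
          zf_product = tq * se[[2L]] * log(10) * .GAS_R * T / .FARADAY)
  structure(list(log_ec50_0 = stats::coef(fit)[[1L]],
                 ec50_0 = 10^stats::coef(fit)[[1L]],
                 zf_product = zf, f_v = zf / z_ca, z_ca = z_ca,
                 ci95 = ci, fit = fit),
            class = "ec50_voltage_fit")
}

#' @export
print.ec50_voltage_fit <- function(x, ...) {
  cat(sprintf("EC50 voltage dependence: EC50(0 mV) = %.4g nM, zCa*fV = %.3g (fV = %.3g for z = %g)\n",
              x$ec50_0, x$zf_product, x$f_v, x$z_ca))
  invisible(x)
}

#' Rundown-corrected concentration-response construction
#'
#' Steady-state test responses are bracketed in time by applications of a
#' saturating reference concentration; each test response is divided by the
#' linear interpolation (in epoch index) of its bracketing reference
#' amplitudes, cancelling slow irreversible rundown, and the corrected
#' responses are normalized to their maximum.
#'
#' @param responses data frame with columns `epoch` (time order), `conc_nM`,
#'   `response`, `is_reference` (logical)
#' @return data frame of corrected test responses (`conc_nM`, `epoch`,
#'   `response`), normalized to the maximal corrected response; unbracketed
#'   test points are dropped with a warning
#' @export
rundown_correct <- function(responses) {
  stopifnot(is.data.frame(responses),
            all(c("epoch", "conc_nM", "response", "is_reference") %in%
                  names(responses)))
  refs <- responses[responses$is_reference, , drop = FALSE]
  tests <- responses[!responses$is_reference, , drop = FALSE]
  if (nrow(refs) < 2L) stop("need >= 2 reference applications", call. = FALSE)
  corrected <- rep(NA_real_, nrow(tests))
  for (i in seq_len(nrow(tests))) {
    e <- tests$epoch[i]
    before <- refs[refs$epoch < e, , drop = FALSE]
    after <- refs[refs$epoch > e, , drop = FALSE]
    if (!nrow(before) || !nrow(after)) next
    b <- before[which.max(before$epoch), ]
    a <- after[which.min(after$epoch), ]
    local_ref <- b$response + (a$response - b$response) *
      (e - b$epoch) / (a$epoch - b$epoch)
    corrected[i] <- tests$response[i] / local_ref
  }
  drop <- is.na(corrected)
  if (any(drop))
    warning(sprintf("%d unbracketed test response(s) excluded", sum(drop)),
            call. = FALSE)
  out <- data.frame(conc_nM = tests$conc_nM[!drop],
                    epoch = tests$epoch[!drop],
                    response = corrected[!drop])
  out$response <- out$response / max(out$response)
  out
}
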