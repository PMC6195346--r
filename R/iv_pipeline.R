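## Data-reduction chain for instantaneous I-V families from inside-out
## patches: pre-pulse (rundown) normalization -> reference-voltage
## normalization -> background subtraction -> model fit -> cross-patch
## aggregation, with bracketed zero-ligand quality control.

.NORM_STATES <- c("raw", "prepulse", "reference", "background-subtracted")

.norm_rank <- function(state) match(state, .NORM_STATES)

#' One patch's instantaneous I-V family at one ligand condition
#'
#' @param patch_id patch identifier
#' @param ligand ligand species tag ("Ca", "Mg", "Gd" or "none")
#' @param conc ligand concentration in nM
#' @param V,I voltages (mV) and instantaneous currents (pA or normalized)
#' @param epoch sweep-train index the recording came from
#' @param prepulse_mV conditioning pre-pulse voltage (mV)
#' @param norm_state one of `"raw"`, `"prepulse"`, `"reference"`,
#'   `"background-subtracted"`; normalization only advances forward
#' @return an object of class `iv_recording`
#' @export
iv_recording <- function(patch_id, ligand, conc, V, I, epoch = 0L,
                         prepulse_mV = 80, norm_state = "raw") {
  stopifnot(length(V) == length(I), is.numeric(V), is.numeric(I))
  if (anyDuplicated(V))
    stop("voltages must be unique within a recording", call. = FALSE)
  norm_state <- match.arg(norm_state, .NORM_STATES)
  ord <- order(V)
  structure(list(patch_id = as.character(patch_id),
                 ligand = as.character(ligand), conc = as.numeric(conc),
                 epoch = as.integer(epoch), prepulse_mV = prepulse_mV,
                 V = as.numeric(V)[ord], I = as.numeric(I)[ord],
                 norm_state = norm_state),
            class = "iv_recording")
}

#' @export
print.iv_recording <- function(x, ...) {
  cat(sprintf("I-V recording: patch %s, %s %g nM, %d voltages [%s]\n",
              x$patch_id, x$ligand, x$conc, length(x$V), x$norm_state))
  invisible(x)
}

.advance_norm <- function(rec, new_state) {
  if (.norm_rank(new_state) < .norm_rank(rec$norm_state))
    stop(sprintf("normalization state cannot go back from '%s' to '%s'",
                 rec$norm_state, new_state), call. = FALSE)
  rec$norm_state <- new_state
  rec
}

#' Pre-pulse (rundown) normalization of a sweep table
#'
#' The current of each sweep is rescaled by the ratio of the recording-median
#' pre-pulse amplitude to that sweep's own pre-pulse amplitude. This corrects
#' multiplicative drift (irreversible rundown) between the sweeps of a train
#' while leaving the relative I-V shape within a sweep untouched. A recording
#' is the set of rows sharing `patch_id` and `epoch`.
#'
#' @param sweeps sweep table as read by [read_sweeps()] (columns `patch_id`,
#'   `epoch`, `ligand`, `conc_nM`, `prepulse_mV`, `prepulse_pA`, `V_mV`,
#'   `I_pA`)
#' @return the sweep table with `I_pA` corrected; sweeps whose pre-pulse
#'   current is zero are dropped with a warning
#' @export
normalize_prepulse <- function(sweeps) {
  .check_sweep_cols(sweeps)
  bad <- sweeps$prepulse_pA == 0
  if (any(bad)) {
    warning(sprintf("%d sweep(s) with zero pre-pulse current excluded",
                    sum(bad)), call. = FALSE)
    sweeps <- sweeps[!bad, , drop = FALSE]
  }
  key <- interaction(sweeps$patch_id, sweeps$epoch, drop = TRUE)
  med <- stats::ave(sweeps$prepulse_pA, key, FUN = stats::median)
  sweeps$I_pA <- sweeps$I_pA * med / sweeps$prepulse_pA
  sweeps
}

#' Normalize a recording to its current at a reference voltage
#'
#' @param rec an [iv_recording()]
#' @param ref_V reference voltage in mV (default +120)
#' @return the recording with all currents divided by I(ref_V); idempotent
#' @export
normalize_reference <- function(rec, ref_V = 120) {
  stopifnot(inherits(rec, "iv_recording"))
  i <- which(abs(rec$V - ref_V) < 1e-9)
  if (length(i) != 1L)
    stop(sprintf("recording has no point at %g mV", ref_V), call. = FALSE)
  if (rec$I[i] == 0)
    stop("current at the reference voltage is zero", call. = FALSE)
  rec$I <- rec$I / rec$I[i]
  .advance_norm(rec, "reference")
}

#' Subtract a zero-ligand background recording
#'
#' Point-wise subtraction of a background (zero-ligand) I-V from a test
#' recording on the same voltage grid; appropriate for constructs without
#' visible basal activity.
#'
#' @param rec test [iv_recording()]
#' @param zero_ligand_rec background [iv_recording()] on the same grid
#' @return the background-subtracted recording
#' @export
background_subtract <- function(rec, zero_ligand_rec) {
  stopifnot(inherits(rec, "iv_recording"),
            inherits(zero_ligand_rec, "iv_recording"))
  if (length(rec$V) != length(zero_ligand_rec$V) ||
      any(abs(rec$V - zero_ligand_rec$V) > 1e-9))
    stop("recordings do not share the voltage grid", call. = FALSE)
  rec$I <- rec$I - zero_ligand_rec$I
  .advance_norm(rec, "background-subtracted")
}

#' Quality-control policy for patch acceptance
#'
#' @param bracket_tol maximal tolerated fractional drift between the
#'   zero-ligand recordings bracketing the test recordings (default 0.2)
#' @param leak_bound maximal tolerated mean zero-ligand current magnitude
#'   at `leak_V` mV, in the units of the sweep table (pA; default 120,
#'   sized for recordings whose saturating current is of order 1 nA)
#' @param leak_V voltage at which leak is assessed (default -100 mV)
#' @param ref_V voltage at which bracket amplitudes are compared (+120 mV)
#' @return a `qc_policy` list
#' @export
qc_policy <- function(bracket_tol = 0.2, leak_bound = 120, leak_V = -100,
                      ref_V = 120) {
  stopifnot(bracket_tol > 0, leak_bound > 0)
  structure(list(bracket_tol = bracket_tol, leak_bound = leak_bound,
                 leak_V = leak_V, ref_V = ref_V), class = "qc_policy")
}

.rec_current_at <- function(rec, V) {
  i <- which(abs(rec$V - V) < 1e-9)
  if (length(i) != 1L) return(NA_real_)
  rec$I[i]
}

#' Quality-control filter on the recordings of one patch
#'
#' Implements the bracketing rule: every recording session must include
#' zero-ligand recordings before and after the test concentrations; a patch
#' is rejected when the bracketing zero-ligand amplitudes drift by more than
#' `policy$bracket_tol` (patch deterioration) or when the mean zero-ligand
#' current at `policy$leak_V` exceeds `policy$leak_bound` (leaky patch).
#' When recordings carry a `prepulse_med` field (as those built by
#' [sweeps_to_recordings()] do), bracket amplitudes are first divided by it,
#' so that ordinary multiplicative rundown - which scales channel current
#' and pre-pulse alike - cancels and the drift test responds to genuine
#' changes in patch quality; without pre-pulse information raw amplitudes
#' are compared.
#'
#' @param recordings list of [iv_recording()] objects from one patch, in
#'   epoch order
#' @param policy a [qc_policy()]
#' @return list with elements `kept` (recordings), `rejected` (recordings)
#'   and `reasons` (character; `"unbracketed"`, `"deteriorated"` or
#'   `"leaky"`; empty when the patch passes)
#' @export
qc_filter <- function(recordings, policy = qc_policy()) {
  stopifnot(is.list(recordings),
            all(vapply(recordings, inherits, TRUE, "iv_recording")))
  epochs <- vapply(recordings, `[[`, 1L, "epoch")
  recordings <- recordings[order(epochs)]
  is_zero <- vapply(recordings, function(r) r$conc == 0, TRUE)
  test <- recordings[!is_zero]
  reasons <- character(0)
  zeros <- recordings[is_zero]
  test_idx <- which(!is_zero)
  zero_idx <- which(is_zero)
  bracketed <- length(test_idx) > 0L && length(zero_idx) >= 2L &&
    any(zero_idx < min(test_idx)) && any(zero_idx > max(test_idx))
  if (!bracketed) {
    reasons <- "unbracketed"
  } else {
    amp <- function(rec) {
      a <- .rec_current_at(rec, policy$ref_V)
      pm <- rec$prepulse_med
      if (!is.null(pm) && is.finite(pm) && pm != 0) a / pm else a
    }
    amps <- vapply(zeros, amp, 0)
    eps <- vapply(zeros, `[[`, 1L, "epoch")
    if (any(is.na(amps))) {
      reasons <- c(reasons, "deteriorated")
    } else {
      ## fitted drift across the session, discounted by twice its standard
      ## error so that measurement noise on small late-session currents does
      ## not masquerade as deterioration
      dfit <- stats::lm(amps ~ eps)
      span <- diff(range(eps))
      drift <- abs(stats::coef(dfit)[[2L]]) * span
      se <- tryCatch(summary(dfit)$coefficients[2L, "Std. Error"] * span,
                     error = function(e) 0)
      if (!is.finite(se)) se <- 0
      denom <- max(mean(abs(amps)), .Machine$double.eps)
      if ((drift - 2 * se) / denom > policy$bracket_tol)
        reasons <- c(reasons, "deteriorated")
    }
    leak <- vapply(zeros, .rec_current_at, 0, policy$leak_V)
    if (mean(abs(leak), na.rm = TRUE) > policy$leak_bound)
      reasons <- c(reasons, "leaky")
  }
  if (length(reasons))
    list(kept = list(), rejected = recordings, reasons = reasons)
  else
    list(kept = test, rejected = list(), reasons = character(0))
}

#' Split a sweep table into I-V recordings
#'
#' @param sweeps sweep table (see [read_sweeps()])
#' @return list of [iv_recording()] objects, one per (patch, epoch)
#' @export
sweeps_to_recordings <- function(sweeps) {
  .check_sweep_cols(sweeps)
  keys <- unique(sweeps[c("patch_id", "epoch")])
  keys <- keys[order(keys$patch_id, keys$epoch), , drop = FALSE]
  lapply(seq_len(nrow(keys)), function(i) {
    s <- sweeps[sweeps$patch_id == keys$patch_id[i] &
                  sweeps$epoch == keys$epoch[i], , drop = FALSE]
    rec <- iv_recording(patch_id = keys$patch_id[i], ligand = s$ligand[1L],
                        conc = s$conc_nM[1L], V = s$V_mV, I = s$I_pA,
                        epoch = keys$epoch[i],
                        prepulse_mV = s$prepulse_mV[1L])
    rec$prepulse_med <- stats::median(s$prepulse_pA)
    rec
  })
}

## -- model fitting ----------------------------------------------------------

.iv_model_resid <- function(theta, V, I, condition, weights) {
  p <- permeation_params(A = exp(theta[1L]), sigma_h = exp(theta[2L]),
                         sigma_beta = exp(theta[3L]), n = 3L,
                         condition = condition)
  (barrier_current(p, V) - I) * sqrt(weights)
}

#' Fit the three-barrier model to an I-V recording
#'
#' Least-squares fit of [barrier_current()] with the barrier count fixed at
#' 3, leaving `sigma_h`, `sigma_beta` and the amplitude factor `A` free. All
#' three parameters are fitted on the log scale to enforce positivity, by
#' Levenberg-Marquardt from multiple starting points on a log-spaced sigma
#' grid (the best residual sum of squares is kept). Confidence intervals are
#' asymptotic: t-based on the log scale from the linearized covariance, then
#' exponentiated, which yields asymmetric intervals respecting positivity;
#' `ci95` additionally reports symmetric half-widths by the delta method.
#'
#' @param rec an [iv_recording()] (or a data frame with columns `V`, `I`)
#' @param condition an [ion_condition()]
#' @param weights optional per-point weights (e.g. 1/sem^2); default
#'   unweighted
#' @param n_starts number of multi-start points (>= 5)
#' @return an object of class `iv_fit` with elements `A`, `sigma_h`,
#'   `sigma_beta`, `ci95` (half-widths), `conf.int` (2.5/97.5% bounds),
#'   `rss`, `df`, `n_fixed = 3`, `converged`
#' @export
fit_iv <- function(rec, condition = ion_condition(), weights = NULL,
                   n_starts = 5L) {
  if (inherits(rec, "iv_recording")) {
    V <- rec$V; I <- rec$I
  } else {
    stopifnot(is.data.frame(rec), all(c("V", "I") %in% names(rec)))
    V <- rec$V; I <- rec$I
  }
  if (length(V) < 6L || min(V) >= 0 || max(V) <= 0)
    stop("need >= 6 voltage points spanning both signs of V", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(V))
  stopifnot(length(weights) == length(V), all(weights > 0))

  sig_grid <- exp(seq(log(0.03), log(3), length.out = max(5L, n_starts)))
  starts <- cbind(sigma_h = rev(sig_grid), sigma_beta = sig_grid)
  vref <- V[which.max(V)]
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    p0 <- permeation_params(A = 1, sigma_h = starts[k, 1L],
                            sigma_beta = starts[k, 2L], condition = condition)
    a0 <- abs(I[which.max(V)] / barrier_current(p0, vref))
    if (!is.finite(a0) || a0 <= 0) a0 <- 1
    th0 <- log(c(a0, starts[k, 1L], starts[k, 2L]))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = .iv_model_resid, V = V, I = I,
                         condition = condition, weights = weights,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    return(structure(list(A = NA_real_, sigma_h = NA_real_,
                          sigma_beta = NA_real_, ci95 = NULL,
                          conf.int = NULL, rss = NA_real_, df = NA_integer_,
                          n_fixed = 3L, converged = FALSE),
                     class = "iv_fit"))
  theta <- best$par
  df <- length(V) - 3L
  s2 <- best$deviance / df
  cov_log <- tryCatch(s2 * solve(best$hessian), error = function(e) NULL)
  se_log <- if (is.null(cov_log)) rep(NA_real_, 3L) else sqrt(diag(cov_log))
  tq <- stats::qt(0.975, df)
  est <- exp(theta)
  names(est) <- c("A", "sigma_h", "sigma_beta")
  ci <- cbind(lower = est * exp(-tq * se_log),
              upper = est * exp(tq * se_log))
  rownames(ci) <- names(est)
  structure(list(A = est[["A"]], sigma_h = est[["sigma_h"]],
                 sigma_beta = est[["sigma_beta"]],
                 ci95 = tq * se_log * est,     # delta-method half-widths
                 conf.int = ci, rss = best$deviance, df = df, n_fixed = 3L,
                 converged = best$info %in% 1:4),
            class = "iv_fit")
}

#' @export
print.iv_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) cat("(fit did not converge)\n")
  cat(sprintf("Three-barrier I-V fit: A = %.4g, sigma_h = %.4g, sigma_beta = %.4g\n",
              x$A, x$sigma_h, x$sigma_beta))
  if (!is.null(x$conf.int)) {
    cat("95% CI (asymptotic, log-scale):\n")
    print(signif(x$conf.int, 4))
  }
  invisible(x)
}

#' Aggregate recordings or fits across patches
#'
#' For a list of recordings sharing a voltage grid, returns the per-voltage
#' mean and s.e.m. of the currents; for a list of `iv_fit` objects, the mean
#' and s.e.m. of each fitted parameter.
#'
#' @param x list of [iv_recording()] or of `iv_fit` objects
#' @return data frame of means and s.e.m. (`sem` is `NA` with a warning for
#'   a single patch)
#' @export
aggregate_patches <- function(x) {
  stopifnot(is.list(x), length(x) >= 1L)
  if (length(x) < 2L) warning("single patch: s.e.m. undefined", call. = FALSE)
  sem <- function(v) if (length(v) < 2L) NA_real_ else
    stats::sd(v) / sqrt(length(v))
  if (inherits(x[[1L]], "iv_recording")) {
    V <- x[[1L]]$V
    for (r in x) if (length(r$V) != length(V) || any(abs(r$V - V) > 1e-9))
      stop("recordings do not share the voltage grid", call. = FALSE)
    m <- vapply(x, `[[`, numeric(length(V)), "I")
    m <- matrix(m, nrow = length(V))
    data.frame(V = V, mean = rowMeans(m), sem = apply(m, 1L, sem),
               n = length(x))
  } else if (inherits(x[[1L]], "iv_fit")) {
    pars <- c("A", "sigma_h", "sigma_beta")
    m <- vapply(x, function(f) unlist(f[pars]), numeric(3L))
    m <- matrix(m, nrow = 3L, dimnames = list(pars, NULL))
    data.frame(parameter = pars, mean = rowMeans(m), sem = apply(m, 1L, sem),
               n = length(x))
  } else stop("unsupported input type", call. = FALSE)
}
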