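## Decomposition of an ensemble I-V curve into open states of differing
## calcium occupancy: I_total = i I_0Ca + j I_1Ca + k I_2Ca, with the basis
## curves given by the three-barrier model at fixed, externally supplied
## parameter sets and the weights estimated by non-negative least squares.

#' Basis of open-state I-V curves for occupancy decomposition
#'
#' @param params_0ca,params_1ca,params_2ca [permeation_params()] describing
#'   the open pore with zero, one and two calcium ions bound; all three
#'   must share the ionic condition
#' @return an object of class `basis_set`
#' @export
basis_set <- function(params_0ca, params_1ca, params_2ca) {
  ps <- list(params_0ca, params_1ca, params_2ca)
  stopifnot(all(vapply(ps, inherits, TRUE, "permeation_params")))
  c0 <- params_0ca$condition
  for (p in ps[-1L])
    if (!identical(unclass(p$condition), unclass(c0)))
      stop("basis parameter sets must share the ionic condition",
           call. = FALSE)
  structure(list(params_0ca = params_0ca, params_1ca = params_1ca,
                 params_2ca = params_2ca), class = "basis_set")
}

#' Default occupancy basis
#'
#' Convenience basis with the package's default open-state shapes: a
#' strongly outwardly rectifying apo state, an intermediate singly occupied
#' state and a pseudo-linear doubly occupied state (amplitude 1 each).
#'
#' @param condition an [ion_condition()]
#' @return a [basis_set()]
#' @export
default_basis_set <- function(condition = ion_condition()) {
  basis_set(
    permeation_params(A = 1, sigma_h = 0.2, sigma_beta = 0.05,
                      condition = condition),
    permeation_params(A = 1, sigma_h = 0.5, sigma_beta = 0.3,
                      condition = condition),
    permeation_params(A = 1, sigma_h = 1, sigma_beta = 1,
                      condition = condition))
}

#' Occupancy-state mixture weights
#'
#' @param i,j,k nonnegative weights of the zero-, one- and two-Ca open
#'   states (they absorb open probability and channel count; no sum-to-one
#'   constraint)
#' @param ci95 optional half-widths
#' @param omit_zero whether `i` was constrained to 0 during fitting
#' @return an object of class `state_weights`
#' @export
state_weights <- function(i = 0, j = 0, k = 0, ci95 = NULL,
                          omit_zero = FALSE) {
  w <- c(i = i, j = j, k = k)
  if (any(!is.finite(w)) || any(w < 0))
    stop("weights must be finite and nonnegative", call. = FALSE)
  structure(list(i = i, j = j, k = k, ci95 = ci95,
                 omit_zero = isTRUE(omit_zero)), class = "state_weights")
}

#' @export
print.state_weights <- function(x, ...) {
  cat(sprintf("Occupancy weights: i (0 Ca) = %.4g%s, j (1 Ca) = %.4g, k (2 Ca) = %.4g\n",
              x$i, if (x$omit_zero) " [fixed]" else "", x$j, x$k))
  invisible(x)
}

## Lawson-Hanson active-set non-negative least squares. Solves
## min ||Ax - b||^2 s.t. x >= 0 exactly (KKT: x_active solves the
## unconstrained subproblem, gradients at the zero bound are nonnegative).
.nnls <- function(A, b, tol = NULL) {
  n <- ncol(A)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(A)) * nrow(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b))          # negative gradient at x = 0
  iter <- 0L
  while (any(!passive & w > tol) && iter < 30L * n) {
    iter <- iter + 1L
    passive[which.max(replace(w, passive, -Inf))] <- TRUE
    lsq <- function(M, y) {            # minimum-norm LS, rank-deficient safe
      s <- svd(M)
      pos <- s$d > max(s$d) * 1e-12
      drop(s$v[, pos, drop = FALSE] %*%
             (crossprod(s$u[, pos, drop = FALSE], y) / s$d[pos]))
    }
    repeat {
      z <- numeric(n)
      z[passive] <- lsq(A[, passive, drop = FALSE], b)
      if (all(z[passive] > tol)) break
      ## step back to the feasible boundary, drop bound-hitting variables
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    x <- z
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

.basis_matrix <- function(basis, voltages) {
  cbind(I0 = barrier_current(basis$params_0ca, voltages),
        I1 = barrier_current(basis$params_1ca, voltages),
        I2 = barrier_current(basis$params_2ca, voltages))
}

#' Compose an I-V curve from occupancy weights
#'
#' @param weights a [state_weights()]
#' @param basis a [basis_set()]
#' @param voltages membrane potentials (mV)
#' @return data frame with columns `V` and `I`
#' @export
compose_iv <- function(weights, basis, voltages) {
  stopifnot(inherits(weights, "state_weights"), inherits(basis, "basis_set"))
  X <- .basis_matrix(basis, voltages)
  data.frame(V = as.numeric(voltages),
             I = drop(X %*% c(weights$i, weights$j, weights$k)))
}

#' Fit occupancy-state weights to an I-V curve
#'
#' Non-negative least squares of the observed currents on the three basis
#' curves. For constructs without measurable basal activity the apo term is
#' omitted (`omit_zero = TRUE`, i fixed at 0). Confidence half-widths for
#' weights strictly inside the feasible region come from the linearized
#' covariance of the active set; weights estimated exactly at the zero bound
#' get an `NA` half-width.
#'
#' @param curve data frame with columns `V` (mV) and `I` (>= 4 voltages)
#' @param basis a [basis_set()]
#' @param omit_zero fix the zero-occupancy weight at 0
#' @return a [state_weights()] with `ci95` and attributes `rss` and
#'   `unidentifiable` (TRUE when the basis is collinear on the grid)
#' @export
fit_state_weights <- function(curve, basis, omit_zero = FALSE) {
  stopifnot(is.data.frame(curve), all(c("V", "I") %in% names(curve)),
            inherits(basis, "basis_set"))
  if (nrow(curve) < 4L) stop("need >= 4 voltages", call. = FALSE)
  X <- .basis_matrix(basis, curve$V)
  sel <- if (omit_zero) 2:3 else 1:3
  Xs <- X[, sel, drop = FALSE]
  unident <- qr(Xs)$rank < ncol(Xs)
  ws <- .nnls(Xs, curve$I)
  w <- numeric(3L)
  w[sel] <- ws
  rss <- sum((curve$I - Xs %*% ws)^2)
  ## linearized covariance over the active (interior) weights
  act <- sel[ws > 0]
  half <- rep(NA_real_, 3L)
  if (length(act)) {
    df <- max(nrow(curve) - length(act), 1L)
    s2 <- rss / df
    covm <- tryCatch(s2 * solve(crossprod(X[, act, drop = FALSE])),
                     error = function(e) NULL)
    if (!is.null(covm))
      half[act] <- stats::qt(0.975, df) * sqrt(diag(covm))
  }
  out <- state_weights(i = w[1L], j = w[2L], k = w[3L],
                       ci95 = c(i = half[1L], j = half[2L], k = half[3L]),
                       omit_zero = omit_zero)
  attr(out, "rss") <- rss
  attr(out, "unidentifiable") <- unident
  out
}

#' Normalized occupancy fractions
#'
#' @param weights a [state_weights()] with at least one positive weight
#' @return named numeric vector `(i, j, k)` summing to 1
#' @export
weight_fractions <- function(weights) {
  stopifnot(inherits(weights, "state_weights"))
  w <- c(i = weights$i, j = weights$j, k = weights$k)
  if (sum(w) <= 0) stop("all weights are zero", call. = FALSE)
  w / sum(w)
}
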