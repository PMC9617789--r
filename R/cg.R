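#' Conjugate-gradient least squares for an encoding operator
#'
#' Solves the (optionally Tikhonov-shifted) normal equations
#' `(A^H A + mu I) x = A^H y + mu z` by conjugate gradients, where `A` is an
#' [encoding_operator()]. With `mu = 0` this is the unregularized
#' least-squares reconstruction; with `mu > 0` it is the data-fidelity
#' subproblem of variable splitting with quadratic penalty, pulling the
#' solution toward the regularizer output `z`.
#'
#' @param op an [encoding_operator()].
#' @param y measured k-space `(coil, readout, phase-encode)`.
#' @param tol stopping tolerance: relative residual of the normal equations.
#' @param max_iter maximum CG iterations.
#' @param mu quadratic-penalty weight (`>= 0`).
#' @param z penalty anchor image stack (required when `mu > 0`).
#' @param x0 optional starting point (defaults to zero).
#' @return list with `x` (image stack `(slice, x, y)`) and `report` (list:
#'   `iterations`, `residual` trace of relative normal-equation residuals,
#'   `converged`).
#' @export
cg_least_squares <- function(op, y, tol = 1e-10, max_iter = 50L,
                             mu = 0, z = NULL, x0 = NULL) {
  if (tol <= 0) stop("tol must be positive")
  if (mu < 0) stop("mu must be nonnegative")
  if (mu > 0 && is.null(z)) stop("z must be supplied when mu > 0")
  b <- op_adjoint(op, y)
  if (mu > 0) {
    if (length(dim(z)) == 2) dim(z) <- c(1L, dim(z))
    b <- b + mu * z
  }
  Afun <- function(v) {
    out <- op_normal(op, v)
    if (mu > 0) out <- out + mu * v
    out
  }
  x <- if (is.null(x0)) array(0 + 0i, dim = dim(b)) else x0
  r <- b - Afun(x)
  p <- r
  rs <- sum(Re(Conj(r) * r))
  b0 <- sqrt(sum(Mod(b)^2))
  if (b0 == 0) b0 <- 1
  res_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Ap <- Afun(p)
    alpha <- rs / sum(Re(Conj(p) * Ap))
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(Re(Conj(r) * r))
    res_trace <- c(res_trace, sqrt(rs_new) / b0)
    if (sqrt(rs_new) / b0 < tol) {
      converged <- TRUE
      rs <- rs_new
      break
    }
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  list(x = x,
       report = list(iterations = it, residual = res_trace,
                     converged = converged))
}

#' Verify the intensity-restoration identity
#'
#' For the unregularized least-squares problems, the conventional solution
#' equals the intensity-restored flat-contrast solution:
#' `xhat_reg = (E^H E)^{-1} E^H y = L * (H^H H)^{-1} H^H y = L * xhat_SIIM`
#' with `H = E L`. This function solves both systems by CG and returns the
#' relative discrepancy `||L * xhat_SIIM - xhat_reg|| / ||xhat_reg||`.
#'
#' @param opE conventional [encoding_operator()].
#' @param opH the matching SIIM operator (`H = E * L`).
#' @param L the [intensity_map()] used in `opH`.
#' @param y measured k-space frame.
#' @param tol CG tolerance used for both solves.
#' @param max_iter CG iteration cap.
#' @return the relative error (scalar).
#' @export
verify_siim_identity <- function(opE, opH, L, y, tol = 1e-10, max_iter = 200L) {
  if (!inherits(L, "intensity_map")) L <- intensity_map(L)
  x_reg <- cg_least_squares(opE, y, tol = tol, max_iter = max_iter)$x
  x_siim <- cg_least_squares(opH, y, tol = tol, max_iter = max_iter)$x
  restored <- x_siim
  for (i in seq_len(dim(x_siim)[1])) {
    restored[i, , ] <- L$values[i, , ] * x_siim[i, , ]
  }
  rel_err(restored, x_reg)
}
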