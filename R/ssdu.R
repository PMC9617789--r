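#' Multi-mask SSDU partition of the sampling pattern
#'
#' Splits the acquired k-space locations Omega into `K` disjoint pairs
#' (Theta_k, Lambda_k): Lambda_k (the loss subset, a fraction `rho` of the
#' acquired points) is drawn without replacement with a Gaussian density
#' preference for points near the k-space center, and Theta_k = Omega \
#' Lambda_k feeds data consistency. A small fully protected central region
#' is kept in every Theta_k so the DC neighborhood never leaves the
#' data-consistency set.
#'
#' @param pattern a [make_sampling_pattern()].
#' @param rho loss-subset fraction in (0, 1) (default 0.4).
#' @param K number of mask pairs (default 6).
#' @param seed RNG seed (identical seeds give identical splits).
#' @param protect_radius half-side of the protected central box in k-space
#'   samples (default 4).
#' @param gauss_sd Gaussian selection bandwidth as a fraction of the grid
#'   (default 0.5).
#' @return an `ssdu_split`: list with logical masks `theta[[k]]`,
#'   `lambda[[k]]` (each `(readout, phase-encode)`), `rho`, `K`.
#' @export
ssdu_partition <- function(pattern, rho = 0.4, K = 6L, seed = 1L,
                           protect_radius = 4L, gauss_sd = 0.5) {
  if (rho <= 0 || rho >= 1) stop("rho must be in (0, 1)")
  if (K < 1) stop("K must be >= 1")
  mask <- pattern$mask
  nx <- nrow(mask); ny <- ncol(mask)
  idx <- which(mask)
  n_take <- round(rho * length(idx))
  if (n_take < 1) stop("rho * |Omega| < 1: nothing to hold out")
  cx <- dc_index(nx); cy <- dc_index(ny)
  rows <- ((idx - 1L) %% nx) + 1L
  cols <- ((idx - 1L) %/% nx) + 1L
  protected <- abs(rows - cx) <= protect_radius & abs(cols - cy) <= protect_radius
  eligible <- which(!protected)
  if (n_take > length(eligible)) n_take <- length(eligible)
  w <- exp(-((rows - cx)^2 / (2 * (gauss_sd * nx)^2) +
               (cols - cy)^2 / (2 * (gauss_sd * ny)^2)))[eligible]
  set.seed(as.integer(seed))
  theta <- lambda <- vector("list", K)
  for (k in seq_len(K)) {
    pick <- sample(eligible, n_take, replace = FALSE, prob = w)
    lam <- matrix(FALSE, nx, ny)
    lam[idx[pick]] <- TRUE
    th <- mask & !lam
    theta[[k]] <- th
    lambda[[k]] <- lam
  }
  structure(list(theta = theta, lambda = lambda, rho = rho, K = as.integer(K),
                 protect_radius = as.integer(protect_radius)),
            class = "ssdu_split")
}

#' Normalized l1-l2 self-supervision loss
#'
#' `||e||_2 / ||y||_2 + ||e||_1 / ||y||_1` with `e = y_meas - y_pred`,
#' evaluated on the held-out subset. Invariant to scaling both arguments by
#' any complex constant.
#'
#' @param y_pred,y_meas complex vectors/arrays restricted to the same
#'   held-out support.
#' @param grad also return the gradient w.r.t. `y_pred` (real-inner-product
#'   convention).
#' @return the scalar loss, or (with `grad`) a list `(loss, g)`.
#' @export
ssdu_loss <- function(y_pred, y_meas, grad = FALSE) {
  if (length(y_meas) == 0) stop("empty held-out subset")
  e <- y_meas - y_pred
  n2 <- sqrt(sum(Mod(y_meas)^2))
  n1 <- sum(Mod(y_meas))
  if (n2 == 0) stop("held-out measurement is identically zero")
  e2 <- sqrt(sum(Mod(e)^2))
  loss <- e2 / n2 + sum(Mod(e)) / n1
  if (!grad) return(loss)
  g2 <- if (e2 > 0) -e / (e2 * n2) else 0 * e
  me <- Mod(e)
  phase <- ifelse(me > 0, e / me, 0 + 0i)
  g1 <- -phase / n1
  list(loss = loss, g = g2 + g1)
}
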