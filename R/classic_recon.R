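# Non-learned dynamic reconstructions: locally low-rank (LLR) regularization
# and the low-rank-plus-sparse (L+S) decomposition. Both use proximal
# gradient iterations with unit step (valid because normalized coil maps give
# ||A^H A|| <= 1) alternating data-consistency gradients with the
# regularizer's proximal map.

# singular-value soft thresholding of a matrix
svt <- function(M, tau) {
  sv <- svd(M)
  d <- pmax(sv$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0 + 0i, nrow(M), ncol(M)))
  sv$u[, keep, drop = FALSE] %*% (d[keep] * Conj(t(sv$v[, keep, drop = FALSE])))
}

# complex soft thresholding (magnitude shrinkage)
soft <- function(x, tau) {
  m <- Mod(x)
  sc <- pmax(m - tau, 0) / pmax(m, .Machine$double.eps)
  x * sc
}

#' Locally low-rank reconstruction of a dynamic series
#'
#' Proximal-gradient reconstruction enforcing low rank of every spatial
#' block's space x time Casorati matrix: each iteration takes a
#' data-consistency gradient step per frame followed by singular-value soft
#' thresholding of (randomly shifted) image blocks. The threshold is
#' `lambda` times the largest block singular value observed at the first
#' iteration, so `lambda` is a relative weight.
#'
#' @param y_series measured k-space `(frame, coil, readout, phase-encode)`
#'   for one SMS group (or single slice).
#' @param ops a single [encoding_operator()] shared by all frames, or a list
#'   with one operator per frame.
#' @param lambda relative singular-value threshold (`0` disables
#'   regularization).
#' @param block_size spatial block side (default 8).
#' @param max_iter outer iterations (default 30).
#' @param seed seed for the random block shifts.
#' @param random_shifts cycle the block grid randomly each iteration
#'   (default `TRUE`); with `FALSE` the partition is fixed and the proximal
#'   gradient objective is guaranteed nonincreasing.
#' @return list with `x` (`(frame, slice, x, y)` complex array) and
#'   `objective` (trace of the regularized objective).
#' @export
llr_reconstruct <- function(y_series, ops, lambda = 0.02, block_size = 8L,
                            max_iter = 30L, seed = 1L, random_shifts = TRUE) {
  nf <- dim(y_series)[1]
  if (nf < 2) stop("need at least 2 frames")
  op1 <- if (inherits(ops, "encoding_operator")) ops else ops[[1]]
  get_op <- function(f) if (inherits(ops, "encoding_operator")) ops else ops[[f]]
  ns <- op1$n_slices; nx <- op1$nx; ny <- op1$ny
  if (block_size > min(nx, ny)) stop("block larger than image")
  set.seed(as.integer(seed))
  b <- array(0 + 0i, dim = c(nf, ns, nx, ny))
  for (f in seq_len(nf))
    b[f, , , ] <- op_adjoint(get_op(f), array(y_series[f, , , ],
                                              dim = dim(y_series)[2:4]))
  x <- b
  tau <- NULL
  nuc_cur <- NULL                        # nuclear norm of the current iterate
  objective <- numeric(0)
  for (it in seq_len(max_iter)) {
    # data-consistency gradient step (unit step; ||A^H A|| <= 1)
    dc <- 0
    for (f in seq_len(nf)) {
      opf <- get_op(f)
      yf <- array(y_series[f, , , ], dim = dim(y_series)[2:4])
      r <- op_forward(opf, array(x[f, , , ], dim = c(ns, nx, ny)))
      dc <- dc + sum(Mod(r - yf)^2)
      g <- op_adjoint(opf, r - yf)
      x[f, , , ] <- array(x[f, , , ], dim = c(ns, nx, ny)) - g
    }
    if (lambda <= 0) {
      objective <- c(objective, dc)
      next
    }
    # record F(x_k): dc is evaluated at the current iterate, the nuclear
    # penalty was computed when that iterate was produced (skip the first
    # iteration, whose threshold is not yet fixed)
    if (!is.null(nuc_cur)) objective <- c(objective, dc + tau * nuc_cur)
    if (random_shifts) {
      sx <- sample.int(block_size, 1L) - 1L
      sy <- sample.int(block_size, 1L) - 1L
    } else {
      sx <- 0L; sy <- 0L
    }
    nuc_cur <- 0
    for (s in seq_len(ns)) {
      arr <- array(x[, s, , ], dim = c(nf, nx, ny))
      res <- .block_svt(arr, block_size, sx, sy, tau, lambda)
      if (is.null(tau)) tau <- res$tau
      x[, s, , ] <- res$arr
      nuc_cur <- nuc_cur + res$nuclear
    }
  }
  list(x = x, objective = objective, tau = tau)
}

# SVT over cyclically shifted blocks of a (frame, nx, ny) array.
.block_svt <- function(arr, bs, sx, sy, tau, lambda) {
  nf <- dim(arr)[1]; nx <- dim(arr)[2]; ny <- dim(arr)[3]
  ix <- ((seq_len(nx) - 1L + sx) %% nx) + 1L   # shifted view
  iy <- ((seq_len(ny) - 1L + sy) %% ny) + 1L
  shifted <- arr[, ix, iy, drop = FALSE]
  nbx <- ceiling(nx / bs); nby <- ceiling(ny / bs)
  nuclear <- 0
  smax <- 0
  for (bxi in seq_len(nbx)) for (byi in seq_len(nby)) {
    xs <- ((bxi - 1L) * bs + 1L):min(bxi * bs, nx)
    ysl <- ((byi - 1L) * bs + 1L):min(byi * bs, ny)
    blk <- matrix(shifted[, xs, ysl], nf, length(xs) * length(ysl))
    M <- t(blk)                                 # space x time Casorati
    if (is.null(tau)) {
      smax <- max(smax, svd(M, nu = 0, nv = 0)$d[1])
      next
    }
    Mt <- svt(M, tau)
    nuclear <- nuclear + sum(svd(Mt, nu = 0, nv = 0)$d)
    shifted[, xs, ysl] <- array(t(Mt), dim = c(nf, length(xs), length(ysl)))
  }
  if (is.null(tau)) {
    tau <- lambda * smax
    # apply with the freshly fixed threshold
    return(.block_svt(arr, bs, sx, sy, tau, lambda))
  }
  arr[, ix, iy] <- shifted
  list(arr = arr, tau = tau, nuclear = nuclear)
}

#' Low-rank plus sparse reconstruction of a dynamic series
#'
#' Decomposes the dynamic series into a globally low-rank background `L` and
#' a dynamic component `S` that is sparse in the temporal (unitary FFT)
#' frequency domain, by iterative soft thresholding with a joint
#' data-consistency gradient each iteration. Thresholds are relative: the
#' singular-value threshold is `lambda_L` times the largest singular value of
#' the initial Casorati matrix, and the sparsity threshold is `lambda_S`
#' times the largest temporal-spectrum magnitude of the initialization.
#'
#' @inheritParams llr_reconstruct
#' @param lambda_L relative singular-value threshold for the low-rank part.
#' @param lambda_S relative soft threshold for the sparse part.
#' @param step gradient step size; the default 0.5 guarantees a monotone
#'   objective (the joint smooth term in (L, S) has Lipschitz constant 2
#'   when `||A^H A|| <= 1`).
#' @return list with `x = L + S` (`(frame, slice, x, y)`), `L_part`,
#'   `S_part`, and `objective` trace.
#' @export
lps_reconstruct <- function(y_series, ops, lambda_L = 0.01, lambda_S = 0.01,
                            max_iter = 40L, step = 0.5) {
  nf <- dim(y_series)[1]
  if (nf < 2) stop("need at least 2 frames")
  op1 <- if (inherits(ops, "encoding_operator")) ops else ops[[1]]
  get_op <- function(f) if (inherits(ops, "encoding_operator")) ops else ops[[f]]
  ns <- op1$n_slices; nx <- op1$nx; ny <- op1$ny
  b <- array(0 + 0i, dim = c(nf, ns, nx, ny))
  for (f in seq_len(nf))
    b[f, , , ] <- op_adjoint(get_op(f), array(y_series[f, , , ],
                                              dim = dim(y_series)[2:4]))
  M0 <- matrix(aperm(b, c(2, 3, 4, 1)), ns * nx * ny, nf)  # Casorati
  sv0 <- svd(M0, nu = 0, nv = 0)$d
  tau_L <- lambda_L * sv0[1]
  spec0 <- t(apply(M0, 1, fft1c))
  tau_S <- lambda_S * max(Mod(spec0))
  Lp <- b; Sp <- array(0 + 0i, dim = dim(b))
  nuc_cur <- sum(sv0); l1_cur <- 0      # penalties of the current iterate
  objective <- numeric(0)
  casorati <- function(a) matrix(aperm(a, c(2, 3, 4, 1)), ns * nx * ny, nf)
  uncasorati <- function(M) aperm(array(M, dim = c(ns, nx, ny, nf)), c(4, 1, 2, 3))
  for (it in seq_len(max_iter)) {
    xk <- Lp + Sp
    dc <- 0
    grad <- array(0 + 0i, dim = dim(b))
    for (f in seq_len(nf)) {
      opf <- get_op(f)
      yf <- array(y_series[f, , , ], dim = dim(y_series)[2:4])
      r <- op_forward(opf, array(xk[f, , , ], dim = c(ns, nx, ny)))
      dc <- dc + sum(Mod(r - yf)^2)
      grad[f, , , ] <- op_adjoint(opf, r - yf)
    }
    objective <- c(objective, dc + tau_L * nuc_cur + tau_S * l1_cur)
    Lh <- casorati(Lp - step * grad)
    Lnew <- svt(Lh, step * tau_L)
    nuc_cur <- sum(svd(Lnew, nu = 0, nv = 0)$d)
    Sh <- casorati(Sp - step * grad)
    spec <- t(apply(Sh, 1, fft1c))
    spec <- soft(spec, step * tau_S)
    l1_cur <- sum(Mod(spec))
    Snew <- t(apply(spec, 1, ifft1c))
    Lp <- uncasorati(Lnew); Sp <- uncasorati(Snew)
  }
  list(x = Lp + Sp, L_part = Lp, S_part = Sp, objective = objective,
       tau_L = tau_L, tau_S = tau_S)
}
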