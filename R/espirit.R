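#' ESPIRiT coil sensitivity maps
#'
#' Eigenvalue-based sensitivity estimation from a calibration k-space region.
#' A block-Hankel calibration matrix is built from sliding `kernel_size`
#' windows; its row space (singular vectors above `eig_threshold` times the
#' largest singular value) is transformed to image space, and the dominant
#' eigenvector of the resulting per-pixel operator gives the sensitivities.
#' Pixels whose eigenvalue falls below `crop_threshold` are outside the coil
#' support and set to zero. Inside the support the maps are normalized to
#' `sum_c |S_c|^2 = 1` and phase-referenced so the first coil is
#' real-positive.
#'
#' @param calib a [calibration_scan()] (or complex array `(slice, coil, kx, ky)`).
#' @param out_size integer length-2 target image grid `(nx, ny)`.
#' @param kernel_size square kernel side (default 6).
#' @param eig_threshold relative singular-value cutoff for the row space
#'   (default 0.02).
#' @param crop_threshold eigenvalue cutoff defining the support (default 0.95).
#' @param calib_size optional central region `(kx, ky)` to use; default all.
#' @return list with `maps` (complex `(slice, coil, nx, ny)`) and `support`
#'   (logical `(slice, nx, ny)`).
#' @export
espirit_maps <- function(calib, out_size, kernel_size = 6L,
                         eig_threshold = 0.02, crop_threshold = 0.95,
                         calib_size = NULL) {
  data <- if (inherits(calib, "calibration_scan")) calib$data else calib
  stopifnot(length(dim(data)) == 4)
  ds <- dim(data)
  n_slices <- ds[1]; n_coils <- ds[2]
  nx <- out_size[1]; ny <- out_size[2]
  k <- as.integer(kernel_size)
  maps <- array(0 + 0i, dim = c(n_slices, n_coils, nx, ny))
  support <- array(FALSE, dim = c(n_slices, nx, ny))
  for (s in seq_len(n_slices)) {
    cal <- array(data[s, , , ], dim = ds[2:4])
    if (!is.null(calib_size)) {
      cal2 <- array(0 + 0i, dim = c(n_coils, calib_size[1], calib_size[2]))
      for (c in seq_len(n_coils))
        cal2[c, , ] <- crop_center(cal[c, , ], calib_size[1], calib_size[2])
      cal <- cal2
    }
    if (all(cal == 0)) stop("degenerate (all-zero) calibration data")
    ckx <- dim(cal)[2]; cky <- dim(cal)[3]
    if (ckx < k || cky < k)
      stop("calibration region smaller than the ESPIRiT kernel")
    res <- .espirit_slice(cal, k, eig_threshold, crop_threshold, nx, ny)
    maps[s, , , ] <- res$maps
    support[s, , ] <- res$support
  }
  list(maps = maps, support = support)
}

.espirit_slice <- function(cal, k, eig_threshold, crop_threshold, nx, ny) {
  n_coils <- dim(cal)[1]; ckx <- dim(cal)[2]; cky <- dim(cal)[3]
  nwx <- ckx - k + 1L; nwy <- cky - k + 1L
  A <- matrix(0 + 0i, nwx * nwy, k * k * n_coils)
  row <- 0L
  for (j in seq_len(nwy)) for (i in seq_len(nwx)) {
    row <- row + 1L
    blk <- cal[, i:(i + k - 1L), j:(j + k - 1L), drop = FALSE]
    A[row, ] <- as.vector(aperm(blk, c(2, 3, 1)))  # (kx, ky, coil) vec order
  }
  sv <- svd(A)
  keep <- which(sv$d > eig_threshold * sv$d[1])
  V <- sv$v[, keep, drop = FALSE]                  # (k*k*C) x n
  n_kern <- ncol(V)
  # image-domain kernels, scaled so support eigenvalues ~ 1
  scale <- sqrt(nx * ny) / sqrt(k * k)
  kerimg <- array(0 + 0i, dim = c(nx, ny, n_coils, n_kern))
  for (v in seq_len(n_kern)) {
    kv <- array(V[, v], dim = c(k, k, n_coils))
    for (c in seq_len(n_coils)) {
      ker <- Conj(kv[, , c])                       # conjugate kernel
      kerimg[, , c, v] <- ifft2c(pad_center(ker, nx, ny)) * scale
    }
  }
  maps <- array(0 + 0i, dim = c(n_coils, nx, ny))
  support <- matrix(FALSE, nx, ny)
  for (jy in seq_len(ny)) for (jx in seq_len(nx)) {
    G <- matrix(kerimg[jx, jy, , ], n_coils, n_kern)  # C x n
    M <- G %*% Conj(t(G))
    eg <- eigen(M, symmetric = TRUE)
    lam <- Re(eg$values[1])
    if (lam >= crop_threshold) {
      u <- eg$vectors[, 1]
      u <- u / sqrt(sum(Mod(u)^2))
      ph <- u[1] / Mod(u[1])
      if (Mod(u[1]) > 0) u <- u * Conj(ph)         # first coil real-positive
      maps[, jx, jy] <- u
      support[jx, jy] <- TRUE
    }
  }
  list(maps = maps, support = support)
}

#' SENSE-1 coil combination
#'
#' Unit-gain sensitivity-weighted combination
#' `sum_c conj(S_c) img_c / max(sum_c |S_c|^2, eps)` evaluated on the coil
#' support (zero outside).
#'
#' @param coil_images complex array `(coil, nx, ny)`.
#' @param maps complex array `(coil, nx, ny)` for the same slice.
#' @param eps denominator floor (default 1e-12).
#' @return complex matrix `(nx, ny)`.
#' @export
sense1_combine <- function(coil_images, maps, eps = 1e-12) {
  stopifnot(all(dim(coil_images) == dim(maps)))
  num <- matrix(0 + 0i, dim(maps)[2], dim(maps)[3])
  den <- matrix(0, dim(maps)[2], dim(maps)[3])
  for (c in seq_len(dim(maps)[1])) {
    num <- num + Conj(maps[c, , ]) * coil_images[c, , ]
    den <- den + Mod(maps[c, , ])^2
  }
  out <- num / pmax(den, eps)
  out[den <= eps] <- 0 + 0i
  out
}
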