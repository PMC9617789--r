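# Split slice-GRAPPA slice separation plus in-plane GRAPPA.
#
# CAIPIRINHA phase cycling is handled through its image-shift equivalent: for
# the kernel fits, each slice's calibration k-space is modulated by the linear
# phase exp(2i*pi * slice * fov_shift * (ky - ky_DC) / R), which is the phase
# the acquisition imparts on the R-spaced sampled lines up to a per-slice
# constant. The linear (shift-invariant) form keeps the fits stationary; the
# per-slice constant is removed analytically at application time.

.caipi_linphase <- function(ny, slice0, fov_shift, R) {
  m <- seq_len(ny) - dc_index(ny)          # ky offset from DC
  exp(2i * pi * slice0 * fov_shift * m / R)
}

#' Calibrate split slice-GRAPPA and in-plane GRAPPA kernels
#'
#' Fits, for every SMS group and every target slice, k-space kernels that
#' predict the target slice's calibration data from the CAIPI-modulated
#' superposition of all slices in the group, with the split constraint that
#' data from any single other slice map to zero (leakage blocking). Source
#' points are spaced `R` lines apart in phase-encode, matching the acquired
#' grid. In-plane GRAPPA kernels that fill the `R - 1` skipped lines are
#' fitted per anatomical slice on the (fully sampled) calibration scan.
#'
#' @param calib a [calibration_scan()] with one entry per anatomical slice.
#' @param protocol an [acq_protocol()].
#' @param kernel_size separation kernel extent `(kx, ky)` in source points
#'   (default `c(5, 7)`; ky sources are `R` lines apart -- the ky tap count
#'   bounds the harmonics of the unmixing weights over the reduced FOV, so
#'   it must grow with `R`).
#' @param inplane_kernel in-plane kernel: `(kx source points, ky source lines)`
#'   (default `c(5, 4)`).
#' @param ridge relative Tikhonov factor for the least-squares fits.
#' @return a `grappa_kernels` object.
#' @export
ssg_calibrate <- function(calib, protocol, kernel_size = c(5L, 7L),
                          inplane_kernel = c(5L, 4L), ridge = 1e-6) {
  validate_protocol(protocol)
  data <- calib$data
  ds <- dim(data)
  sms <- protocol$n_slices_per_group
  n_groups <- protocol$n_groups
  if (ds[1] != sms * n_groups)
    stop("calibration must provide one slice per anatomical slice")
  n_coils <- ds[2]; ckx <- ds[3]; cky <- ds[4]
  R <- protocol$in_plane_R
  fs <- protocol$fov_shift_fraction
  kx <- kernel_size[1]; ky <- kernel_size[2]
  hx <- (kx - 1L) %/% 2L
  span_y <- R * (ky - 1L) + 1L
  min_ck <- c(kx, span_y)
  if (ckx < kx || cky < span_y)
    stop(sprintf("calibration too small for separation kernels: need at least %dx%d, got %dx%d",
                 min_ck[1], min_ck[2], ckx, cky))
  sep <- vector("list", n_groups)
  for (g in seq_len(n_groups)) {
    slices <- (g - 1L) * sms + seq_len(sms)
    # modulated calibration per slice in the group
    modcal <- array(0 + 0i, dim = c(sms, n_coils, ckx, cky))
    for (i in seq_len(sms)) {
      ph <- .caipi_linphase(cky, i - 1L, fs, R)
      for (c in seq_len(n_coils))
        modcal[i, c, , ] <- sweep(data[slices[i], c, , ], 2, ph, `*`)
    }
    sep[[g]] <- .fit_sep_kernels(modcal, kx, ky, R, ridge)
  }
  ip <- vector("list", ds[1])
  for (s in seq_len(ds[1])) {
    ip[[s]] <- .fit_inplane_kernels(array(data[s, , , ], dim = ds[2:4]),
                                    R, inplane_kernel[1], inplane_kernel[2], ridge)
  }
  structure(list(sep = sep, inplane = ip,
                 kernel_size = c(kx, ky), inplane_kernel = inplane_kernel,
                 R = R, fov_shift = fs, sms = sms, n_groups = n_groups,
                 n_coils = n_coils),
            class = "grappa_kernels")
}

# Fit separation kernels for one group. modcal: (sms, coil, ckx, cky).
# Returns array (kx*ky*coil, coil, sms): weights per target slice.
.fit_sep_kernels <- function(modcal, kx, ky, R, ridge) {
  sms <- dim(modcal)[1]; n_coils <- dim(modcal)[2]
  ckx <- dim(modcal)[3]; cky <- dim(modcal)[4]
  hx <- (kx - 1L) %/% 2L
  hy <- (ky - 1L) %/% 2L
  xs <- (hx + 1L):(ckx - hx)
  ys <- (R * hy + 1L):(cky - R * hy)
  n_rows_per <- length(xs) * length(ys)
  nun <- kx * ky * n_coils
  # source rows for each individual slice (split constraint needs them apart)
  S_list <- vector("list", sms)
  tgt <- array(0 + 0i, dim = c(sms, n_rows_per, n_coils))
  dy <- R * ((-hy):hy)
  dxs <- (-hx):hx
  for (i in seq_len(sms)) {
    S <- matrix(0 + 0i, n_rows_per, nun)
    row <- 0L
    for (y0 in ys) for (x0 in xs) {
      row <- row + 1L
      blk <- modcal[i, , x0 + dxs, y0 + dy, drop = FALSE]  # (1, coil, kx, ky)
      S[row, ] <- as.vector(aperm(array(blk, dim = c(n_coils, kx, ky)), c(2, 3, 1)))
      tgt[i, row, ] <- modcal[i, , x0, y0]
    }
    S_list[[i]] <- S
  }
  W <- array(0 + 0i, dim = c(nun, n_coils, sms))
  # split constraint: stack per-slice sources; target is the slice's own
  # calibration for i == target slice, zero otherwise
  A <- do.call(rbind, S_list)
  AhA <- Conj(t(A)) %*% A
  lam <- ridge * Re(sum(diag(AhA))) / nun
  AhA <- AhA + diag(lam, nun)
  for (i in seq_len(sms)) {
    B <- matrix(0 + 0i, sms * n_rows_per, n_coils)
    B[(i - 1L) * n_rows_per + seq_len(n_rows_per), ] <- tgt[i, , ]
    W[, , i] <- solve(AhA, Conj(t(A)) %*% B)
  }
  W
}

# Fit in-plane kernels for one slice. cal: (coil, ckx, cky).
# For each offset d in 1..R-1 predict line a+d from lines a + R*(-1,0,1,2).
# Returns list over d of arrays (kx*nsrc*coil, coil).
.fit_inplane_kernels <- function(cal, R, kx, nsrc, ridge) {
  if (R == 1L) return(list())
  n_coils <- dim(cal)[1]; ckx <- dim(cal)[2]; cky <- dim(cal)[3]
  hx <- (kx - 1L) %/% 2L
  srcy <- R * (seq_len(nsrc) - nsrc %/% 2L)       # e.g. (-R, 0, R, 2R) for nsrc=4
  nun <- kx * nsrc * n_coils
  out <- vector("list", R - 1L)
  dxs <- (-hx):hx
  for (d in seq_len(R - 1L)) {
    ylo <- max(1L - min(srcy), 1L)
    yhi <- min(cky - max(srcy), cky - d)
    xs <- (hx + 1L):(ckx - hx)
    ys <- ylo:yhi
    if (length(ys) < 2L || length(xs) < 1L)
      stop(sprintf("calibration too small for in-plane kernels (need ky extent > %d)",
                   max(srcy) - min(srcy) + d))
    n_rows <- length(xs) * length(ys)
    if (n_rows < nun)
      stop(sprintf("in-plane GRAPPA fit underdetermined: %d equations for %d unknowns; enlarge the calibration region",
                   n_rows, nun))
    A <- matrix(0 + 0i, n_rows, nun)
    B <- matrix(0 + 0i, n_rows, n_coils)
    row <- 0L
    for (y0 in ys) for (x0 in xs) {
      row <- row + 1L
      blk <- cal[, x0 + dxs, y0 + srcy, drop = FALSE]
      A[row, ] <- as.vector(aperm(array(blk, dim = c(n_coils, kx, nsrc)), c(2, 3, 1)))
      B[row, ] <- cal[, x0, y0 + d]
    }
    AhA <- Conj(t(A)) %*% A
    lam <- ridge * Re(sum(diag(AhA))) / nun
    out[[d]] <- solve(AhA + diag(lam, nun), Conj(t(A)) %*% B)
  }
  out
}

#' Apply split slice-GRAPPA separation and in-plane filling
#'
#' Separates one SMS-collapsed, undersampled k-space frame into per-slice
#' k-spaces and fills the skipped in-plane lines inside the partial-Fourier
#' window. Acquired locations of the collapsed data are never altered before
#' separation; the unacquired partial-Fourier band stays zero.
#'
#' @param kernels a [ssg_calibrate()] result.
#' @param y collapsed k-space frame `(coil, readout, phase-encode)`.
#' @param pattern the frame's [make_sampling_pattern()].
#' @param group which SMS group the frame belongs to.
#' @param fill_inplane fill skipped lines with in-plane GRAPPA (default TRUE).
#' @return complex array `(slice_in_group, coil, readout, phase-encode)`.
#' @export
ssg_apply <- function(kernels, y, pattern, group = 1L, fill_inplane = TRUE) {
  stopifnot(inherits(kernels, "grappa_kernels"))
  n_coils <- dim(y)[1]; nx <- dim(y)[2]; ny <- dim(y)[3]
  if (n_coils != kernels$n_coils) stop("coil count mismatch with kernels")
  R <- kernels$R
  cols <- pattern$sampled_cols
  if (length(cols) >= 2 && any(diff(cols) != R))
    stop("sampling pattern does not match the kernel line spacing R")
  sms <- kernels$sms
  kx <- kernels$kernel_size[1]; ky <- kernels$kernel_size[2]
  hx <- (kx - 1L) %/% 2L; hy <- (ky - 1L) %/% 2L
  nsamp <- length(cols)
  # compact acquired grid (readout x acquired-line index)
  ys <- array(0 + 0i, dim = c(n_coils, nx, nsamp))
  for (c in seq_len(n_coils)) ys[c, , ] <- y[c, , cols]
  W <- kernels$sep[[group]]
  out <- array(0 + 0i, dim = c(sms, n_coils, nx, ny))
  dxs <- (-hx):hx; dys <- (-hy):hy
  # slide the separation kernel over the compact grid (zero-padded borders)
  src <- matrix(0 + 0i, nx * nsamp, kx * ky * n_coils)
  colidx <- 0L
  for (c in seq_len(n_coils)) for (dy in dys) for (dx in dxs) {
    colidx <- colidx + 1L
    shifted <- matrix(0 + 0i, nx, nsamp)
    x_rng <- max(1, 1 + dx):min(nx, nx + dx)
    j_rng <- max(1, 1 + dy):min(nsamp, nsamp + dy)
    shifted[x_rng - dx, j_rng - dy] <- ys[c, x_rng, j_rng]
    src[, colidx] <- as.vector(shifted)
  }
  # column order (dx fastest, then dy, then coil) matches the fit's
  # (kx, ky, coil) vectorization
  for (i in seq_len(sms)) {
    pred <- src %*% W[, , i]                     # (nx*nsamp) x coil
    # undo the linear CAIPI phase and the per-slice acquisition constant
    lin <- .caipi_linphase(ny, i - 1L, kernels$fov_shift, R)[cols]
    const <- exp(2i * pi * (i - 1L) * kernels$fov_shift *
                   (dc_index(ny) - cols[1]) / R)
    for (c in seq_len(n_coils)) {
      plane <- matrix(pred[, c], nx, nsamp)
      plane <- sweep(plane, 2, Conj(lin * const), `*`)
      out[i, c, , cols] <- plane
    }
  }
  if (fill_inplane && R > 1L) {
    slices <- (group - 1L) * sms + seq_len(sms)
    for (i in seq_len(sms)) {
      out[i, , , ] <- .inplane_fill(kernels$inplane[[slices[i]]],
                                    array(out[i, , , ], dim = c(n_coils, nx, ny)),
                                    cols, pattern$window_cols, R,
                                    kernels$inplane_kernel)
    }
  }
  out
}

.inplane_fill <- function(ipk, kdata, cols, window_cols, R, geom) {
  n_coils <- dim(kdata)[1]; nx <- dim(kdata)[2]; ny <- dim(kdata)[3]
  kx <- geom[1]; nsrc <- geom[2]
  hx <- (kx - 1L) %/% 2L
  srcy <- R * (seq_len(nsrc) - nsrc %/% 2L)
  dxs <- (-hx):hx
  missing_cols <- setdiff(window_cols, cols)
  for (t in missing_cols) {
    d <- ((t - cols[1]) %% R)
    if (d == 0L) next
    a <- t - d
    src_cols <- a + srcy
    A <- matrix(0 + 0i, nx, kx * nsrc * n_coils)
    colidx <- 0L
    for (c in seq_len(n_coils)) for (sy in src_cols) for (dx in dxs) {
      colidx <- colidx + 1L
      v <- rep(0 + 0i, nx)
      if (sy >= 1 && sy <= ny && sy %in% cols) {
        x_rng <- max(1, 1 + dx):min(nx, nx + dx)
        v[x_rng - dx] <- kdata[c, x_rng, sy]
      }
      A[, colidx] <- v
    }
    pred <- A %*% ipk[[d]]
    for (c in seq_len(n_coils)) kdata[c, , t] <- pred[, c]
  }
  kdata
}
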