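#' Separable 2-D Blackman window
#'
#' Product of two 1-D Blackman windows, used to apodize the central k-space
#' block before zero-padding so the low-resolution intensity image is free of
#' ringing.
#'
#' @param nx,ny window lengths.
#' @return numeric matrix `(nx, ny)` with values in `[0, 1]`.
#' @export
blackman2 <- function(nx, ny) {
  bl <- function(n) {
    if (n == 1) return(1)
    m <- seq_len(n) - 1L
    0.42 - 0.5 * cos(2 * pi * m / (n - 1)) + 0.08 * cos(4 * pi * m / (n - 1))
  }
  outer(bl(nx), bl(ny))
}

#' Build the per-frame intensity map L
#'
#' Constructs the diagonal payload of the signal-intensity-informed operator
#' for one SMS group and time frame: the collapsed frame is separated with
#' split slice-GRAPPA, the central `calib_size` k-space block is apodized
#' with a separable Blackman window and zero-padded to the full matrix, the
#' unitary inverse FFT gives low-resolution coil images, and the magnitude of
#' their SENSE-1 combination is the intensity map of each slice.
#'
#' @param y collapsed k-space frame `(coil, readout, phase-encode)`.
#' @param kernels a [ssg_calibrate()] result.
#' @param maps ESPIRiT maps `(slice_total, coil, nx, ny)` (see
#'   [espirit_maps()]); the group's slices are selected internally.
#' @param pattern the frame's [make_sampling_pattern()].
#' @param group SMS group index.
#' @param calib_size central block size `(kx, ky)` (default 24 x 24).
#' @param floor_frac relative floor for [intensity_map()].
#' @param window apodization matrix; default [blackman2()] of `calib_size`.
#' @return an [intensity_map()] with values `(slice_in_group, nx, ny)`.
#' @export
make_intensity_map <- function(y, kernels, maps, pattern, group = 1L,
                               calib_size = c(24L, 24L), floor_frac = 1e-3,
                               window = NULL) {
  if (all(y == 0)) stop("all-zero k-space frame")
  n_coils <- dim(y)[1]; nx <- dim(y)[2]; ny <- dim(y)[3]
  sms <- kernels$sms
  sep <- ssg_apply(kernels, y, pattern, group = group, fill_inplane = TRUE)
  if (is.null(window)) window <- blackman2(calib_size[1], calib_size[2])
  slices <- (group - 1L) * sms + seq_len(sms)
  L <- array(0, dim = c(sms, nx, ny))
  for (i in seq_len(sms)) {
    imgs <- array(0 + 0i, dim = c(n_coils, nx, ny))
    for (c in seq_len(n_coils)) {
      blk <- crop_center(sep[i, c, , ], calib_size[1], calib_size[2]) * window
      imgs[c, , ] <- ifft2c(pad_center(blk, nx, ny))
    }
    comb <- sense1_combine(imgs, array(maps[slices[i], , , ],
                                       dim = c(n_coils, nx, ny)))
    L[i, , ] <- Mod(comb)
  }
  intensity_map(L, floor_frac = floor_frac)
}
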