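#' Acquisition protocol description
#'
#' Bundles the scan geometry and acceleration settings that every other
#' component consumes: matrix size, coil count, SMS factor and number of SMS
#' groups, frame count, uniform in-plane acceleration `R`, partial-Fourier
#' fraction, CAIPIRINHA FOV-shift fraction, and calibration-region size.
#'
#' The default values correspond to the accelerated SMS perfusion protocol the
#' package targets: SMS factor 3 with FOV/3 CAIPIRINHA shifts, four-fold
#' uniform in-plane undersampling with no autocalibration block, and 6/8
#' partial Fourier (net 16-fold acceleration over a slice group).
#'
#' @param matrix_size integer length-2: readout x phase-encode pixels.
#' @param n_coils number of receive coils.
#' @param n_slices_per_group SMS (multiband) factor.
#' @param n_groups number of SMS slice groups covering the heart.
#' @param n_frames number of dynamic time frames.
#' @param in_plane_R integer uniform in-plane acceleration factor.
#' @param partial_fourier acquired fraction of phase-encode space, in (0.5, 1].
#' @param fov_shift_fraction CAIPIRINHA inter-slice FOV shift; must be
#'   `p / n_slices_per_group` for an integer `p`.
#' @param calib_size integer length-2 calibration-region size (kx x ky).
#' @return an object of class `acq_protocol` (a validated list).
#' @export
acq_protocol <- function(matrix_size = c(160L, 120L),
                         n_coils = 8L,
                         n_slices_per_group = 3L,
                         n_groups = 3L,
                         n_frames = 40L,
                         in_plane_R = 4L,
                         partial_fourier = 6 / 8,
                         fov_shift_fraction = 1 / 3,
                         calib_size = c(24L, 24L)) {
  p <- list(
    matrix_size = as.integer(matrix_size),
    n_coils = as.integer(n_coils),
    n_slices_per_group = as.integer(n_slices_per_group),
    n_groups = as.integer(n_groups),
    n_frames = as.integer(n_frames),
    in_plane_R = as.integer(in_plane_R),
    partial_fourier = partial_fourier,
    fov_shift_fraction = fov_shift_fraction,
    calib_size = as.integer(rep(calib_size, length.out = 2))
  )
  class(p) <- "acq_protocol"
  validate_protocol(p)
  p
}

validate_protocol <- function(p) {
  stopifnot(inherits(p, "acq_protocol"))
  if (length(p$matrix_size) != 2 || any(p$matrix_size < 1))
    stop("matrix_size must be two positive integers")
  if (p$in_plane_R < 1) stop("in_plane_R must be >= 1")
  if (p$partial_fourier < 0.5 || p$partial_fourier > 1)
    stop("partial_fourier must lie in [0.5, 1]")
  pshift <- p$fov_shift_fraction * p$n_slices_per_group
  if (abs(pshift - round(pshift)) > 1e-9)
    stop("fov_shift_fraction must be p/n_slices_per_group for integer p")
  if (any(p$calib_size > p$matrix_size))
    stop("calib_size cannot exceed matrix_size")
  if (p$n_slices_per_group < 1 || p$n_groups < 1 || p$n_coils < 1 || p$n_frames < 1)
    stop("counts must be positive")
  invisible(p)
}

#' Total number of anatomical slices covered by a protocol
#'
#' Slice accounting: `n_groups` SMS groups times the SMS factor, e.g. three
#' groups of three simultaneously excited slices reconstruct 9 slices per
#' frame.
#'
#' @param protocol an [acq_protocol()].
#' @return integer slice count.
#' @export
n_total_slices <- function(protocol) {
  validate_protocol(protocol)
  protocol$n_groups * protocol$n_slices_per_group
}

#' Enumerate self-supervised training samples
#'
#' Training operates on individual SMS-encoded k-space frames. Following the
#' training split used for this protocol, the first frames (pre-contrast
#' calibration of the dynamic range) are dropped and the remaining frames of
#' every SMS group of every training subject form the sample pool, e.g.
#' 4 subjects x 3 groups x last 35 of 40 frames = 420 samples.
#'
#' @param n_subjects number of training subjects.
#' @param n_groups SMS groups per subject.
#' @param n_frames frames per series.
#' @param frames_used number of (final) frames retained per series.
#' @return data.frame with columns `subject`, `group`, `frame`.
#' @export
enumerate_training_samples <- function(n_subjects, n_groups, n_frames,
                                       frames_used = n_frames) {
  stopifnot(frames_used <= n_frames, frames_used >= 1)
  frames <- seq.int(n_frames - frames_used + 1L, n_frames)
  expand.grid(frame = frames, group = seq_len(n_groups),
              subject = seq_len(n_subjects))[, c("subject", "group", "frame")]
}

#' Image series container
#'
#' A complex array `(slice, frame, x, y)` tagged with the domain it lives in:
#' `"siim"` for flat-contrast solutions of the intensity-informed system,
#' `"restored"` after multiplication by the intensity map, or
#' `"coil-combined"` for conventional solutions.
#'
#' @param data complex 4-D array `(slice, frame, x, y)`.
#' @param domain one of `"siim"`, `"restored"`, `"coil-combined"`.
#' @return an `image_series` object.
#' @export
image_series <- function(data, domain = c("coil-combined", "siim", "restored")) {
  domain <- match.arg(domain)
  stopifnot(length(dim(data)) == 4)
  structure(data, domain = domain, class = c("image_series", class(data)))
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_series> %d slice(s) x %d frame(s) x %dx%d [%s]\n",
              d[1], d[2], d[3], d[4], attr(x, "domain")))
  invisible(x)
}

#' Reconstruction configuration
#'
#' Plumbing record for solver and training hyper-parameters; every output
#' artifact of the pipeline records the configuration and seed it was produced
#' with.
#'
#' @param method one of `"ssg"`, `"llr"`, `"lps"`, `"pgdl-conv"`, `"pgdl-siim"`, `"cg"`.
#' @param cg_tol CG stopping tolerance on the relative normal-equation residual.
#' @param cg_iters maximum CG iterations per data-consistency solve.
#' @param n_unrolls unroll count of the variable-splitting network.
#' @param lambda regularization weight (meaning depends on method).
#' @param seed RNG seed recorded in artifacts.
#' @param extra named list of method-specific settings.
#' @return a `recon_config` list.
#' @export
recon_config <- function(method = "cg", cg_tol = 1e-6, cg_iters = 15L,
                         n_unrolls = 10L, lambda = 0.01, seed = 1L,
                         extra = list()) {
  stopifnot(method %in% c("ssg", "llr", "lps", "pgdl-conv", "pgdl-siim", "cg"))
  if (cg_tol <= 0) stop("tolerances must be positive")
  structure(list(method = method, cg_tol = cg_tol, cg_iters = as.integer(cg_iters),
                 n_unrolls = as.integer(n_unrolls), lambda = lambda,
                 seed = as.integer(seed), extra = extra),
            class = "recon_config")
}
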