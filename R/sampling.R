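#' Uniform undersampling pattern with partial Fourier
#'
#' Builds the boolean phase-encode sampling mask for one time frame: uniform
#' step-`R` lines (no autocalibration block) restricted to the asymmetric
#' partial-Fourier window. Partial Fourier is modeled purely as
#' non-acquisition of the early phase-encode fraction; the retained window
#' always contains DC. The mask is identical across coils and across the
#' readout direction.
#'
#' @param protocol an [acq_protocol()].
#' @param frame_index 1-based frame index; the sampled residue class can
#'   rotate with the frame when `rotate_offset = TRUE`.
#' @param pe_offset which residue class (0-based, mod `R`) of the window is
#'   sampled; default 0 and constant across frames.
#' @param rotate_offset if `TRUE`, `pe_offset` advances by one per frame.
#' @return a `sampling_pattern`: list with the logical `mask`
#'   `(readout x phase-encode)`, the sampled 1-based column indices
#'   `sampled_cols`, the partial-Fourier window, `in_plane_R`,
#'   `partial_fourier`, and `pe_offset`.
#' @export
make_sampling_pattern <- function(protocol, frame_index = 1L, pe_offset = 0L,
                                  rotate_offset = FALSE) {
  validate_protocol(protocol)
  nx <- protocol$matrix_size[1]
  ny <- protocol$matrix_size[2]
  R <- protocol$in_plane_R
  if (R > ny) stop("in_plane_R exceeds the number of phase-encode lines")
  off <- as.integer(pe_offset) %% R
  if (rotate_offset) off <- (off + (as.integer(frame_index) - 1L)) %% R
  # partial-Fourier window: drop the early fraction, keep the DC side
  win0 <- as.integer(round(ny * (1 - protocol$partial_fourier)))  # 0-based first kept line
  win <- seq.int(win0, ny - 1L)  # 0-based kept window
  sampled0 <- win[(win - win0) %% R == off]  # 0-based sampled lines
  mask <- matrix(FALSE, nx, ny)
  mask[, sampled0 + 1L] <- TRUE
  structure(list(mask = mask,
                 sampled_cols = sampled0 + 1L,
                 window_cols = win + 1L,
                 in_plane_R = R,
                 partial_fourier = protocol$partial_fourier,
                 pe_offset = off),
            class = "sampling_pattern")
}

#' Net acceleration factor of a sampling scheme
#'
#' Over a slice group, the acceleration is the SMS factor times the ratio of
#' total phase-encode lines to acquired lines. For SMS factor 3, R = 4 and
#' 6/8 partial Fourier this is exactly 16.
#'
#' @param pattern a [make_sampling_pattern()] result.
#' @param sms_factor number of simultaneously excited slices.
#' @return the net acceleration (fold).
#' @export
acceleration_factor <- function(pattern, sms_factor = 1L) {
  stopifnot(inherits(pattern, "sampling_pattern"))
  n_sampled <- length(pattern$sampled_cols)
  if (n_sampled == 0) stop("empty sampling mask")
  sms_factor * ncol(pattern$mask) / n_sampled
}

#' CAIPIRINHA phase schedule
#'
#' Per-slice RF phase cycling across acquired phase-encode lines: the j-th
#' sampled line (0-based) of slice i (0-based) receives phase
#' `2*pi*i*j*fov_shift_fraction`. Slice 0 carries no phase; for a FOV shift of
#' 1/3 the phases of slice 1 cycle through `{0, 2pi/3, 4pi/3}` on consecutive
#' sampled lines. In image space this shifts the aliased position of slice i
#' by `i * fov_shift_fraction` of the (reduced) field of view.
#'
#' @param protocol an [acq_protocol()].
#' @param pattern the frame's [make_sampling_pattern()]; defaults to frame 1.
#' @return a `caipi_schedule`: list with `phases` (matrix
#'   `n_slices x n_sampled_lines`, radians) and per-slice complex phase
#'   columns aligned to the full phase-encode grid (`phase_grid`,
#'   `n_slices x n_pe`, equal to 1 on unsampled columns).
#' @export
make_caipi_schedule <- function(protocol, pattern = NULL) {
  validate_protocol(protocol)
  if (is.null(pattern)) pattern <- make_sampling_pattern(protocol)
  ns <- protocol$n_slices_per_group
  fs <- protocol$fov_shift_fraction
  j <- seq_along(pattern$sampled_cols) - 1L
  phases <- outer(seq_len(ns) - 1L, j, function(i, j) (2 * pi * i * j * fs) %% (2 * pi))
  ny <- ncol(pattern$mask)
  phase_grid <- matrix(1 + 0i, ns, ny)
  for (i in seq_len(ns)) {
    phase_grid[i, pattern$sampled_cols] <- exp(1i * phases[i, ])
  }
  structure(list(phases = phases, phase_grid = phase_grid,
                 fov_shift_fraction = fs),
            class = "caipi_schedule")
}
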