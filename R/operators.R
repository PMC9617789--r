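#' Per-frame intensity map (diagonal of L)
#'
#' Nonnegative real pixel values per slice holding the signal-intensity
#' information of one time frame. Flooring guarantees strict positivity so
#' that division by L (intensity restoration of the flat-contrast solution)
#' is well defined; the floor is `floor_frac * max(L)` per slice.
#'
#' @param values numeric array `(slice, x, y)`, nonnegative.
#' @param floor_frac relative floor applied per slice (default 1e-3).
#' @return an `intensity_map` with floored `values`.
#' @export
intensity_map <- function(values, floor_frac = 1e-3) {
  if (length(dim(values)) == 2) dim(values) <- c(1L, dim(values))
  stopifnot(length(dim(values)) == 3)
  if (any(values < 0)) stop("intensity map values must be nonnegative")
  v <- values
  for (i in seq_len(dim(v)[1])) {
    m <- max(v[i, , ])
    if (m == 0) stop("intensity map slice is identically zero")
    v[i, , ] <- pmax(v[i, , ], floor_frac * m)
  }
  structure(list(values = v, floor_frac = floor_frac), class = "intensity_map")
}

#' Multi-coil SMS encoding operator
#'
#' Constructs the linear operator mapping a per-slice image stack to the
#' acquired, SMS-collapsed, undersampled multi-coil k-space of one frame.
#' The conventional kind is the SENSE model
#' `y_c = M ( sum_i P_i * F(S_ci * x_i) )` with unitary FFT `F`, sampling mask
#' `M`, coil maps `S`, and CAIPIRINHA per-line phases `P_i`; the SIIM
#' ("signal-intensity-informed") kind composes it with a diagonal intensity
#' map, `H = E * L`, so the solved-for image has flat contrast across frames.
#'
#' @param maps complex coil maps `(slice, coil, x, y)`.
#' @param pattern a [make_sampling_pattern()].
#' @param caipi a [make_caipi_schedule()]; `NULL` for no phase cycling.
#' @param kind `"conventional"` or `"siim"`.
#' @param L an [intensity_map()] (required for kind `"siim"`).
#' @return an `encoding_operator`.
#' @export
encoding_operator <- function(maps, pattern, caipi = NULL,
                              kind = c("conventional", "siim"), L = NULL) {
  kind <- match.arg(kind)
  d <- dim(maps)
  stopifnot(length(d) == 4)
  if (!identical(dim(pattern$mask), d[3:4]) &&
      !all(dim(pattern$mask) == d[3:4]))
    stop("mask dimensions do not match coil maps")
  if (kind == "siim") {
    if (is.null(L)) stop("siim operator requires an intensity map L")
    if (!inherits(L, "intensity_map")) L <- intensity_map(L)
    if (!all(dim(L$values) == d[c(1, 3, 4)]))
      stop("intensity map dimensions do not match coil maps")
  }
  n_slices <- d[1]
  if (is.null(caipi)) {
    phase_grid <- matrix(1 + 0i, n_slices, d[4])
  } else {
    phase_grid <- caipi$phase_grid
    stopifnot(nrow(phase_grid) == n_slices)
  }
  structure(list(kind = kind, maps = maps, pattern = pattern,
                 phase_grid = phase_grid, L = L,
                 n_slices = n_slices, n_coils = d[2],
                 nx = d[3], ny = d[4]),
            class = "encoding_operator")
}

# expand a per-slice phase-encode phase row to a full (nx, ny) grid
.phase_plane <- function(op, i) {
  matrix(op$phase_grid[i, ], op$nx, op$ny, byrow = TRUE)
}

.apply_L <- function(op, x) {
  for (i in seq_len(op$n_slices)) x[i, , ] <- op$L$values[i, , ] * x[i, , ]
  x
}

#' Forward and adjoint encoding
#'
#' `op_forward` maps an image slice stack `(slice, x, y)` to masked k-space
#' `(coil, readout, phase-encode)`; `op_adjoint` is its exact Hermitian
#' adjoint (inner-product consistent to machine precision). For the SIIM kind
#' the forward is `E(L * x)` and the adjoint `L * E^H(y)` (L real diagonal,
#' hence self-adjoint). `op_normal` composes the two.
#'
#' @param op an [encoding_operator()].
#' @param x complex array `(slice, x, y)` (a matrix is accepted for one slice).
#' @param y complex array `(coil, readout, phase-encode)`.
#' @return `op_forward`: k-space array; `op_adjoint`/`op_normal`: image stack.
#' @export
op_forward <- function(op, x) {
  if (length(dim(x)) == 2) dim(x) <- c(1L, dim(x))
  stopifnot(all(dim(x) == c(op$n_slices, op$nx, op$ny)))
  if (op$kind == "siim") x <- .apply_L(op, x)
  y <- array(0 + 0i, dim = c(op$n_coils, op$nx, op$ny))
  for (i in seq_len(op$n_slices)) {
    ph <- .phase_plane(op, i)
    xi <- x[i, , ]
    for (c in seq_len(op$n_coils)) {
      y[c, , ] <- y[c, , ] + fft2c(op$maps[i, c, , ] * xi) * ph
    }
  }
  mask <- op$pattern$mask
  for (c in seq_len(op$n_coils)) y[c, , ][!mask] <- 0 + 0i
  y
}

#' @rdname op_forward
#' @export
op_adjoint <- function(op, y) {
  stopifnot(all(dim(y) == c(op$n_coils, op$nx, op$ny)))
  x <- array(0 + 0i, dim = c(op$n_slices, op$nx, op$ny))
  mask <- op$pattern$mask
  for (i in seq_len(op$n_slices)) {
    phc <- Conj(.phase_plane(op, i))
    acc <- matrix(0 + 0i, op$nx, op$ny)
    for (c in seq_len(op$n_coils)) {
      yc <- y[c, , ]
      yc[!mask] <- 0 + 0i
      acc <- acc + Conj(op$maps[i, c, , ]) * ifft2c(yc * phc)
    }
    x[i, , ] <- acc
  }
  if (op$kind == "siim") x <- .apply_L(op, x)
  x
}

#' @rdname op_forward
#' @export
op_normal <- function(op, x) {
  op_adjoint(op, op_forward(op, x))
}

#' Restrict an operator's sampling to a sub-mask
#'
#' Returns a copy of `op` whose mask is the elementwise AND of the original
#' mask and `submask`. Used for the data-consistency split of self-supervised
#' training.
#'
#' @param op an [encoding_operator()].
#' @param submask logical matrix `(readout, phase-encode)`.
#' @return an [encoding_operator()].
#' @export
op_restrict <- function(op, submask) {
  stopifnot(all(dim(submask) == dim(op$pattern$mask)))
  op$pattern$mask <- op$pattern$mask & submask
  op
}
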