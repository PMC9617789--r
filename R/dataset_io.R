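# On-disk dataset layout (HDF5):
#   /kspace      double, dims (2, frame, group, coil, readout, pe); leading
#                axis is re/im (the HDF5 library in use has no complex type)
#   /calibration double, dims (2, slice, coil, kx, ky)
#   /mask        uint8 (readout, pe)
#   /caipi_phase double (n_slices_per_group, n_sampled_lines), radians
#   root attributes: matrix_size, n_coils, sms_factor, n_groups, n_frames,
#                    in_plane_R, partial_fourier (two ints), fov_shift (two
#                    ints), calib_size, seed, software_version
# Complex data are stored in arbitrary signal units; any normalization applied
# upstream is the caller's to record (attribute `normalization` if given).

c2ri <- function(x) {
  out <- array(0, dim = c(2L, dim(x)))
  idx <- slice.index(out, 1)
  out[idx == 1L] <- Re(x)
  out[idx == 2L] <- Im(x)
  out
}

ri2c <- function(x) {
  d <- dim(x)
  idx <- slice.index(x, 1)
  z <- complex(real = x[idx == 1L], imaginary = x[idx == 2L])
  array(z, dim = d[-1])
}

#' Multi-coil SMS k-space container
#'
#' Acquired, SMS-collapsed, undersampled k-space with its sampling pattern.
#' Entries at unsampled locations must be exactly zero (zero signal at a
#' sampled location is legal; a nonzero unsampled entry is a layout
#' violation).
#'
#' @param data complex array `(frame, group, coil, readout, phase-encode)`.
#' @param pattern the [make_sampling_pattern()] shared by all coils/frames.
#' @return a `kspace_sms` object.
#' @export
kspace_sms <- function(data, pattern) {
  stopifnot(length(dim(data)) == 5, inherits(pattern, "sampling_pattern"))
  d <- dim(data)
  if (!all(d[4:5] == dim(pattern$mask)))
    stop("k-space grid does not match the sampling mask")
  off <- !pattern$mask
  for (f in seq_len(d[1])) for (g in seq_len(d[2])) for (c in seq_len(d[3])) {
    plane <- data[f, g, c, , ]
    if (any(plane[off] != 0))
      stop("unsampled k-space entries must be exactly zero")
  }
  structure(list(data = data, pattern = pattern), class = "kspace_sms")
}

#' Per-slice calibration scan
#'
#' Low-resolution, fully sampled multi-coil k-space acquired separately for
#' every anatomical slice; used for coil-map estimation and GRAPPA kernel
#' calibration.
#'
#' @param data complex array `(slice, coil, kx, ky)`.
#' @return a `calibration_scan` object.
#' @export
calibration_scan <- function(data) {
  stopifnot(length(dim(data)) == 4)
  structure(list(data = data), class = "calibration_scan")
}

.proto_attrs <- function(protocol, seed) {
  pf <- .as_rational(protocol$partial_fourier)
  fs <- .as_rational(protocol$fov_shift_fraction)
  list(matrix_size = protocol$matrix_size,
       n_coils = protocol$n_coils,
       sms_factor = protocol$n_slices_per_group,
       n_groups = protocol$n_groups,
       n_frames = protocol$n_frames,
       in_plane_R = protocol$in_plane_R,
       partial_fourier = pf,
       fov_shift = fs,
       calib_size = protocol$calib_size,
       seed = as.integer(seed),
       software_version = as.character(utils::packageVersion("siimrecon")))
}

# smallest-denominator rational p/q (q <= 64) for protocol fractions
.as_rational <- function(x) {
  for (q in 1:64) {
    p <- x * q
    if (abs(p - round(p)) < 1e-9) return(c(as.integer(round(p)), as.integer(q)))
  }
  stop("fraction is not a small rational: ", x)
}

#' Write a dataset to HDF5
#'
#' Persists a protocol, collapsed k-space series, and calibration scan in the
#' package's HDF5 layout (see the source header of `dataset_io.R`). The file
#' records the protocol, seed and software version as root attributes so that
#' every derived artifact is reproducible.
#'
#' @param path output file path (`.h5`).
#' @param protocol an [acq_protocol()].
#' @param kspace a [kspace_sms()].
#' @param calib a [calibration_scan()].
#' @param seed integer seed recorded in the file.
#' @param force overwrite an existing file (default `FALSE`: error).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(path, protocol, kspace, calib, seed = 0L,
                          force = FALSE) {
  validate_protocol(protocol)
  stopifnot(inherits(kspace, "kspace_sms"), inherits(calib, "calibration_scan"))
  if (file.exists(path) && !force)
    stop("refusing to overwrite existing file (use force = TRUE): ", path)
  if (file.exists(path)) unlink(path)
  ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
  if (isFALSE(ok)) stop("cannot write dataset at ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(c2ri(kspace$data), path, "kspace")
  rhdf5::h5write(c2ri(calib$data), path, "calibration")
  rhdf5::h5write(array(as.integer(kspace$pattern$mask),
                       dim = dim(kspace$pattern$mask)), path, "mask")
  caipi <- make_caipi_schedule(protocol, kspace$pattern)
  rhdf5::h5write(caipi$phases, path, "caipi_phase")
  fid <- rhdf5::H5Fopen(path)
  at <- .proto_attrs(protocol, seed)
  for (nm in names(at)) rhdf5::h5writeAttribute(at[[nm]], fid, nm)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

.require_h5 <- function(path, name) {
  ls <- rhdf5::h5ls(path, recursive = FALSE)$name
  if (!(name %in% ls))
    stop(sprintf("dataset format error: missing group '%s' in %s", name, path))
}

#' Read a dataset from HDF5
#'
#' Inverse of [write_dataset()]: validates layout and invariants and
#' reconstructs the protocol, k-space container (with its sampling pattern),
#' and calibration scan. A missing group or attribute raises a format error
#' naming the missing key; inconsistent dimensions raise a validation error.
#'
#' @param path HDF5 file written by [write_dataset()].
#' @return list with elements `protocol`, `kspace`, `calib`, `seed`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset not found: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  for (g in c("kspace", "calibration", "mask", "caipi_phase"))
    .require_h5(path, g)
  at <- rhdf5::h5readAttributes(path, "/")
  need <- c("matrix_size", "n_coils", "sms_factor", "n_groups", "n_frames",
            "in_plane_R", "partial_fourier", "fov_shift", "calib_size", "seed")
  miss <- setdiff(need, names(at))
  if (length(miss))
    stop("dataset format error: missing attribute(s) ", paste(miss, collapse = ", "))
  protocol <- acq_protocol(
    matrix_size = as.integer(at$matrix_size),
    n_coils = as.integer(at$n_coils),
    n_slices_per_group = as.integer(at$sms_factor),
    n_groups = as.integer(at$n_groups),
    n_frames = as.integer(at$n_frames),
    in_plane_R = as.integer(at$in_plane_R),
    partial_fourier = at$partial_fourier[1] / at$partial_fourier[2],
    fov_shift_fraction = at$fov_shift[1] / at$fov_shift[2],
    calib_size = as.integer(at$calib_size))
  kdata <- ri2c(rhdf5::h5read(path, "kspace"))
  cdata <- ri2c(rhdf5::h5read(path, "calibration"))
  maskv <- rhdf5::h5read(path, "mask")
  d <- dim(kdata)
  expect <- c(protocol$n_frames, protocol$n_groups, protocol$n_coils,
              protocol$matrix_size)
  if (!all(d == expect))
    stop("dataset validation error: k-space dims (", paste(d, collapse = "x"),
         ") do not match protocol (", paste(expect, collapse = "x"), ")")
  if (!all(dim(maskv) == protocol$matrix_size))
    stop("dataset validation error: mask dims do not match protocol")
  pattern <- .pattern_from_mask(maskv == 1, protocol)
  ks <- kspace_sms(kdata, pattern)  # enforces zero-filled unsampled entries
  list(protocol = protocol, kspace = ks,
       calib = calibration_scan(cdata), seed = as.integer(at$seed))
}

# Rebuild a sampling_pattern object from a stored boolean mask.
.pattern_from_mask <- function(mask, protocol) {
  cols <- which(apply(mask, 2, any))
  ny <- ncol(mask)
  win0 <- as.integer(round(ny * (1 - protocol$partial_fourier)))
  structure(list(mask = mask, sampled_cols = cols,
                 window_cols = seq.int(win0 + 1L, ny),
                 in_plane_R = protocol$in_plane_R,
                 partial_fourier = protocol$partial_fourier,
                 pe_offset = if (length(cols)) (cols[1] - 1L - win0) %% protocol$in_plane_R else 0L),
            class = "sampling_pattern")
}

#' Validate dataset invariants
#'
#' Report-only checker: returns a character vector naming every violated
#' invariant (empty if all pass). Checks dimensional consistency, zero
#' filling of unsampled entries, the arithmetic-progression structure of the
#' sampling pattern against the protocol's `R`, and calibration coverage of
#' the protocol's calibration region.
#'
#' @param protocol an [acq_protocol()].
#' @param kspace a [kspace_sms()].
#' @param calib a [calibration_scan()].
#' @param pattern a [make_sampling_pattern()]; defaults to the k-space's own.
#' @return character vector of violations (possibly empty).
#' @export
validate_dataset <- function(protocol, kspace, calib, pattern = kspace$pattern) {
  report <- character(0)
  d <- dim(kspace$data)
  expect <- c(protocol$n_frames, protocol$n_groups, protocol$n_coils,
              protocol$matrix_size)
  if (!all(d == expect))
    report <- c(report, "kspace dimensions do not match protocol")
  off <- !pattern$mask
  bad <- FALSE
  for (f in seq_len(d[1])) for (g in seq_len(d[2])) for (c in seq_len(d[3])) {
    if (any(kspace$data[f, g, c, , ][off] != 0)) bad <- TRUE
  }
  if (bad) report <- c(report, "nonzero entries at unsampled k-space locations")
  cols <- pattern$sampled_cols
  if (length(cols) >= 2) {
    steps <- diff(cols)
    if (length(unique(steps)) != 1 || steps[1] != protocol$in_plane_R)
      report <- c(report,
                  sprintf("sampling pattern inconsistent with in_plane_R=%d (observed line spacing %s)",
                          protocol$in_plane_R, paste(unique(steps), collapse = ",")))
  }
  dc <- dim(calib$data)
  if (dc[1] != n_total_slices(protocol))
    report <- c(report, "calibration must hold one entry per anatomical slice")
  if (any(dc[3:4] < protocol$calib_size))
    report <- c(report, sprintf("calibration region (%dx%d) smaller than calib_size (%dx%d)",
                                dc[3], dc[4], protocol$calib_size[1], protocol$calib_size[2]))
  report
}

#' Persist derived calibration products into a dataset file
#'
#' Writes ESPIRiT coil maps and per-frame intensity maps into the
#' `/derived` group of an existing dataset written by [write_dataset()], so
#' a reconstruction can be reproduced without re-running calibration.
#'
#' @param path HDF5 dataset file.
#' @param maps complex coil maps `(slice, coil, x, y)` or `NULL`.
#' @param L_maps nested list `L_maps[[group]][[frame]]` of [intensity_map()]s
#'   or `NULL`.
#' @return `path`, invisibly.
#' @export
write_derived_maps <- function(path, maps = NULL, L_maps = NULL) {
  if (!file.exists(path)) stop("dataset not found: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path, recursive = FALSE)$name
  if (!("derived" %in% ls)) rhdf5::h5createGroup(path, "derived")
  if (!is.null(maps)) rhdf5::h5write(c2ri(maps), path, "derived/maps")
  if (!is.null(L_maps)) {
    ng <- length(L_maps); nf <- length(L_maps[[1]])
    d1 <- dim(L_maps[[1]][[1]]$values)
    arr <- array(0, dim = c(ng, nf, d1))
    for (g in seq_len(ng)) for (f in seq_len(nf))
      arr[g, f, , , ] <- L_maps[[g]][[f]]$values
    rhdf5::h5write(arr, path, "derived/L")
  }
  invisible(path)
}

#' Read derived calibration products from a dataset file
#'
#' @param path HDF5 dataset file with a `/derived` group.
#' @return list with `maps` (complex array or `NULL`) and `L` (numeric array
#'   `(group, frame, slice, x, y)` or `NULL`).
#' @export
read_derived_maps <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)$name
  out <- list(maps = NULL, L = NULL)
  if ("maps" %in% ls) out$maps <- ri2c(rhdf5::h5read(path, "derived/maps"))
  if ("L" %in% ls) out$L <- rhdf5::h5read(path, "derived/L")
  out
}
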