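#' Peak signal-to-noise ratio
#'
#' `PSNR = 20 log10(max|ref| / RMSE)` computed on magnitude images. Identical
#' inputs return `Inf`.
#'
#' @param x,ref images (complex or real) of identical shape.
#' @return PSNR in dB.
#' @export
psnr <- function(x, ref) {
  if (!all(dim(x) == dim(ref) | is.null(dim(x)))) stop("shape mismatch")
  mref <- max(Mod(ref))
  if (mref == 0) stop("reference image is identically zero")
  rmse <- sqrt(mean((Mod(x) - Mod(ref))^2))
  if (rmse == 0) return(Inf)
  20 * log10(mref / rmse)
}

#' Structural similarity index
#'
#' Mean SSIM of the magnitude images over a sliding uniform window
#' (default 7 x 7) with the standard stabilization constants
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`; the dynamic range `L` is the larger
#' of the two image maxima, making the metric symmetric.
#'
#' @param x,ref images of identical shape (2-D).
#' @param window odd window side (default 7).
#' @return mean SSIM (unitless, `<= 1`).
#' @export
ssim <- function(x, ref, window = 7L) {
  if (!all(dim(x) == dim(ref))) stop("shape mismatch")
  a <- Mod(x); b <- Mod(ref)
  L <- max(max(a), max(b))
  if (L == 0) stop("both images are identically zero")
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  w <- window
  mu_a <- .boxfilt(a, w); mu_b <- .boxfilt(b, w)
  va <- .boxfilt(a * a, w) - mu_a^2
  vb <- .boxfilt(b * b, w) - mu_b^2
  cab <- .boxfilt(a * b, w) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s)
}

# uniform box filter with "valid" handling via edge-cropped means
.boxfilt <- function(m, w) {
  h <- (w - 1L) %/% 2L
  nx <- nrow(m); ny <- ncol(m)
  # pad by edge replication, then cumulative-sum box filter
  px <- m[c(rep(1L, h), seq_len(nx), rep(nx, h)), , drop = FALSE]
  px <- px[, c(rep(1L, h), seq_len(ny), rep(ny, h)), drop = FALSE]
  cs <- apply(px, 2, cumsum)
  cs <- rbind(0, cs)
  colsum <- cs[seq_len(nx) + w, ] - cs[seq_len(nx), ]
  cs2 <- t(apply(colsum, 1, cumsum))
  cs2 <- cbind(0, cs2)
  out <- cs2[, seq_len(ny) + w] - cs2[, seq_len(ny)]
  out / (w * w)
}

#' ROI uptake curve with zero-phase low-pass filtering
#'
#' Per-frame mean of the image magnitude over a region of interest, low-pass
#' filtered along time with a zero-phase (forward-backward) Hamming-windowed
#' sinc FIR whose DC gain is exactly 1, so constant series pass unchanged.
#'
#' @param images an [image_series()] or complex array `(slice, frame, x, y)`.
#' @param roi logical matrix `(x, y)` selecting the ROI.
#' @param slice which slice to analyze.
#' @param cutoff low-pass cutoff in cycles/frame (default 0.15); `NULL`
#'   disables filtering.
#' @param taps FIR length (odd, default 11).
#' @return list with `raw` and `filtered` numeric vectors (length `n_frames`)
#'   and the `roi`.
#' @export
uptake_curve <- function(images, roi, slice = 1L, cutoff = 0.15, taps = 11L) {
  d <- dim(images)
  if (!all(dim(roi) == d[3:4])) stop("ROI does not match the image grid")
  if (!any(roi)) stop("ROI is empty")
  nf <- d[2]
  raw <- vapply(seq_len(nf), function(f) mean(Mod(images[slice, f, , ])[roi]),
                numeric(1))
  if (is.null(cutoff)) return(list(raw = raw, filtered = raw, roi = roi))
  h <- .fir_lowpass(cutoff, taps)
  filtered <- .filtfilt(raw, h)
  list(raw = raw, filtered = filtered, roi = roi)
}

# Hamming-windowed sinc FIR, DC gain normalized to exactly 1.
.fir_lowpass <- function(cutoff, taps = 11L) {
  stopifnot(taps %% 2 == 1)
  n <- seq_len(taps) - 1L
  m <- (taps - 1) / 2
  x <- n - m
  h <- ifelse(x == 0, 2 * cutoff, sin(2 * pi * cutoff * x) / (pi * x))
  w <- 0.54 - 0.46 * cos(2 * pi * n / (taps - 1))
  h <- h * w
  h / sum(h)
}

# zero-phase filtering: reflect-pad, filter forward and backward
.filtfilt <- function(v, h) {
  n <- length(v)
  m <- length(h)
  pad <- m
  ext <- c(rev(v[seq_len(min(pad, n))]), v, rev(v[n + 1 - seq_len(min(pad, n))]))
  fwd <- stats::filter(ext, h, sides = 2)
  bwd <- rev(stats::filter(rev(fwd), h, sides = 2))
  out <- bwd[pad + seq_len(n)]
  # edges where the kernel ran off the padding: fall back to raw values
  out[is.na(out)] <- v[is.na(out)]
  as.numeric(out)
}
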