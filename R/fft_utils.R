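# Centered, unitary 2-D FFT helpers.
#
# Convention: DC at 1-based index floor(N/2)+1 on both axes; forward and
# inverse transforms are scaled by 1/sqrt(N) so they are unitary.

circshift_idx <- function(n, s) ((seq_len(n) - 1L - s) %% n) + 1L

#' Shift DC from the first index to the array center (and back)
#'
#' `fftshift2` moves the DC sample from index 1 to `floor(N/2)+1` on both
#' axes of a matrix; `ifftshift2` is its exact inverse (they differ for odd
#' lengths).
#'
#' @param x a matrix (real or complex).
#' @return a matrix of the same dimensions.
#' @keywords internal
fftshift2 <- function(x) {
  d <- dim(x)
  x[circshift_idx(d[1], floor(d[1] / 2)), circshift_idx(d[2], floor(d[2] / 2)), drop = FALSE]
}

#' @rdname fftshift2
#' @keywords internal
ifftshift2 <- function(x) {
  d <- dim(x)
  x[circshift_idx(d[1], -floor(d[1] / 2)), circshift_idx(d[2], -floor(d[2] / 2)), drop = FALSE]
}

#' Centered unitary 2-D Fourier transforms
#'
#' `fft2c` maps a DC-centered image to DC-centered k-space; `ifft2c` is its
#' inverse. Both are unitary: `sum(abs(fft2c(x))^2) == sum(abs(x)^2)` to
#' machine precision.
#'
#' @param x complex (or real) matrix.
#' @return complex matrix of the same dimensions.
#' @export
fft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))
}

#' @rdname fft2c
#' @export
ifft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / sqrt(length(x))
}

# 1-D centered unitary FFT along a vector (used for temporal transforms).
fft1c <- function(v) {
  n <- length(v)
  s <- floor(n / 2)
  vs <- v[circshift_idx(n, -s)]
  (stats::fft(vs) / sqrt(n))[circshift_idx(n, s)]
}

ifft1c <- function(v) {
  n <- length(v)
  s <- floor(n / 2)
  vs <- v[circshift_idx(n, -s)]
  (stats::fft(vs, inverse = TRUE) / sqrt(n))[circshift_idx(n, s)]
}

# DC index (1-based) for a length-n k-space axis.
dc_index <- function(n) floor(n / 2) + 1L

# Centered crop / zero-pad of a matrix in k-space, keeping DC aligned.
crop_center <- function(x, nx, ny) {
  d <- dim(x)
  ix <- dc_index(d[1]) + seq_len(nx) - dc_index(nx)
  iy <- dc_index(d[2]) + seq_len(ny) - dc_index(ny)
  stopifnot(ix[1] >= 1, ix[nx] <= d[1], iy[1] >= 1, iy[ny] <= d[2])
  x[ix, iy, drop = FALSE]
}

pad_center <- function(x, nx, ny) {
  d <- dim(x)
  out <- array(0 + 0i, dim = c(nx, ny))
  ix <- dc_index(nx) + seq_len(d[1]) - dc_index(d[1])
  iy <- dc_index(ny) + seq_len(d[2]) - dc_index(d[2])
  out[ix, iy] <- x
  out
}

# Relative L2 error between two arrays.
rel_err <- function(a, b) {
  db <- sqrt(sum(Mod(b)^2))
  if (db == 0) return(sqrt(sum(Mod(a - b)^2)))
  sqrt(sum(Mod(a - b)^2)) / db
}

# Real inner product on complex arrays: Re<a, b>.
re_inner <- function(a, b) sum(Re(Conj(a) * b))
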