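# Residual convolutional regularizer operating on two-channel (re/im) real
# images, with hand-written backpropagation on top of the Rcpp conv kernels.
#
# Architecture: input convolution (2 -> F), `n_blocks` residual blocks
# [conv -> ReLU -> conv -> x scale, + skip], output convolution (F -> 2),
# and a global skip from input to output. All kernels are 3x3; weights are
# shared across unrolled iterations by construction (a single weight list).

#' Initialize regularizer weights
#'
#' @param n_blocks number of residual blocks (default 15).
#' @param n_filters channels per layer (default 64).
#' @param kernel kernel side (default 3).
#' @param scale residual scaling constant (default 0.1).
#' @param init `"he"` for random He-scaled initialization or `"zero"` for
#'   zero residual/output paths (the network is then exactly the identity).
#' @param zero_output with `init = "he"`, zero the output convolution so the
#'   freshly initialized network is exactly the identity (the unrolled
#'   reconstruction then starts as a proximal-point chain and training
#'   learns a residual correction); default `FALSE`.
#' @param seed RNG seed for the initialization.
#' @return a `resnet_weights` list.
#' @export
resnet_init <- function(n_blocks = 15L, n_filters = 64L, kernel = 3L,
                        scale = 0.1, init = c("he", "zero"),
                        zero_output = FALSE, seed = 1L) {
  init <- match.arg(init)
  set.seed(as.integer(seed))
  mk <- function(ci, co) {
    if (init == "zero") {
      array(0, dim = c(kernel, kernel, ci, co))
    } else {
      array(rnorm(kernel * kernel * ci * co, sd = sqrt(2 / (kernel * kernel * ci))),
            dim = c(kernel, kernel, ci, co))
    }
  }
  blocks <- lapply(seq_len(n_blocks), function(i)
    list(w1 = mk(n_filters, n_filters), b1 = numeric(n_filters),
         w2 = mk(n_filters, n_filters), b2 = numeric(n_filters)))
  w_out <- if (zero_output) array(0, dim = c(kernel, kernel, n_filters, 2L)) else mk(n_filters, 2L)
  structure(list(
    w_in = mk(2L, n_filters), b_in = numeric(n_filters),
    blocks = blocks,
    w_out = w_out, b_out = numeric(2L),
    scale = scale, n_blocks = as.integer(n_blocks),
    n_filters = as.integer(n_filters), kernel = as.integer(kernel)),
    class = "resnet_weights")
}

#' Apply the residual regularizer to a two-channel image
#'
#' @param x real array `(H, W, 2)` (re/im channels).
#' @param wt a [resnet_init()] weight list.
#' @param keep_cache retain intermediates for [resnet_backward()].
#' @return real array `(H, W, 2)`; with `keep_cache = TRUE`, attribute
#'   `"cache"` holds the forward intermediates.
#' @export
resnet_forward <- function(x, wt, keep_cache = FALSE) {
  stopifnot(length(dim(x)) == 3, dim(x)[3] == 2)
  cache <- if (keep_cache) list(x = x) else NULL
  h <- conv2d_fwd(x, wt$w_in, wt$b_in)
  if (keep_cache) cache$h_in <- h
  hs <- if (keep_cache) vector("list", wt$n_blocks) else NULL
  for (i in seq_len(wt$n_blocks)) {
    bl <- wt$blocks[[i]]
    u <- conv2d_fwd(h, bl$w1, bl$b1)
    v <- u * (u > 0)
    w2o <- conv2d_fwd(v, bl$w2, bl$b2)
    if (keep_cache) hs[[i]] <- list(h = h, u = u, v = v)
    h <- h + wt$scale * w2o
  }
  out_conv <- conv2d_fwd(h, wt$w_out, wt$b_out)
  out <- x + out_conv
  if (keep_cache) {
    cache$blocks <- hs
    cache$h_last <- h
    attr(out, "cache") <- cache
  }
  out
}

#' Backpropagate through the residual regularizer
#'
#' @param gout gradient of a scalar loss w.r.t. the network output,
#'   real array `(H, W, 2)`.
#' @param wt the weights used in the forward pass.
#' @param cache the `"cache"` attribute of [resnet_forward()] output.
#' @return list with `gx` (gradient w.r.t. the input) and `grads` (structure
#'   parallel to `wt` holding the weight gradients).
#' @export
resnet_backward <- function(gout, wt, cache) {
  grads <- list(w_in = NULL, b_in = NULL, blocks = vector("list", wt$n_blocks),
                w_out = NULL, b_out = NULL)
  gx <- gout                                   # global skip
  bw_out <- conv2d_bwd(cache$h_last, wt$w_out, gout)
  grads$w_out <- bw_out$gw; grads$b_out <- bw_out$gb
  gh <- bw_out$gx
  for (i in rev(seq_len(wt$n_blocks))) {
    bl <- wt$blocks[[i]]
    st <- cache$blocks[[i]]
    gw2o <- wt$scale * gh
    bw2 <- conv2d_bwd(st$v, bl$w2, gw2o)
    gv <- bw2$gx
    gu <- gv * (st$u > 0)
    bw1 <- conv2d_bwd(st$h, bl$w1, gu)
    grads$blocks[[i]] <- list(w1 = bw1$gw, b1 = bw1$gb,
                              w2 = bw2$gw, b2 = bw2$gb)
    gh <- gh + bw1$gx                          # block skip
  }
  bw_in <- conv2d_bwd(cache$x, wt$w_in, gh)
  grads$w_in <- bw_in$gw; grads$b_in <- bw_in$gb
  gx <- gx + bw_in$gx
  list(gx = gx, grads = grads)
}

# ---- weight-list arithmetic helpers (flat vector view for the optimizer) ----

resnet_flatten <- function(wt) {
  v <- c(as.vector(wt$w_in), wt$b_in)
  for (bl in wt$blocks) v <- c(v, as.vector(bl$w1), bl$b1, as.vector(bl$w2), bl$b2)
  c(v, as.vector(wt$w_out), wt$b_out)
}

resnet_unflatten <- function(v, wt) {
  pos <- 0L
  take <- function(n) {
    out <- v[pos + seq_len(n)]
    pos <<- pos + n
    out
  }
  wt$w_in <- array(take(length(wt$w_in)), dim = dim(wt$w_in))
  wt$b_in <- take(length(wt$b_in))
  for (i in seq_along(wt$blocks)) {
    bl <- wt$blocks[[i]]
    bl$w1 <- array(take(length(bl$w1)), dim = dim(bl$w1))
    bl$b1 <- take(length(bl$b1))
    bl$w2 <- array(take(length(bl$w2)), dim = dim(bl$w2))
    bl$b2 <- take(length(bl$b2))
    wt$blocks[[i]] <- bl
  }
  wt$w_out <- array(take(length(wt$w_out)), dim = dim(wt$w_out))
  wt$b_out <- take(length(wt$b_out))
  stopifnot(pos == length(v))
  wt
}

grads_flatten <- function(grads) {
  v <- c(as.vector(grads$w_in), grads$b_in)
  for (bl in grads$blocks) v <- c(v, as.vector(bl$w1), bl$b1, as.vector(bl$w2), bl$b2)
  c(v, as.vector(grads$w_out), grads$b_out)
}

#' Count trainable parameters of the regularizer (plus the penalty scalar)
#'
#' @param wt a [resnet_init()] weight list.
#' @param include_mu count the trainable penalty weight as one parameter.
#' @return integer parameter count.
#' @export
resnet_n_params <- function(wt, include_mu = TRUE) {
  length(resnet_flatten(wt)) + as.integer(include_mu)
}

# ---- complex <-> two-channel conversion and SMS slice concatenation ----
# The slice stack (slice, x, y) is concatenated along the readout direction
# before entering the network and split back afterwards. `shifts` optionally
# undoes per-slice CAIPIRINHA FOV shifts (cyclic, in pixels along
# phase-encode); the default operator formulation keeps slices in their true
# positions, so the default shift is zero.

concat_slices <- function(x, shifts = NULL) {
  ns <- dim(x)[1]; nx <- dim(x)[2]; ny <- dim(x)[3]
  if (is.null(shifts)) shifts <- rep(0L, ns)
  out <- array(0 + 0i, dim = c(ns * nx, ny))
  for (i in seq_len(ns)) {
    xi <- x[i, , ]
    s <- shifts[i] %% ny
    if (s != 0) xi <- xi[, c((s + 1):ny, 1:s), drop = FALSE]
    out[(i - 1L) * nx + seq_len(nx), ] <- xi
  }
  out
}

split_slices <- function(m, ns, shifts = NULL) {
  nxt <- nrow(m); ny <- ncol(m)
  nx <- nxt / ns
  if (is.null(shifts)) shifts <- rep(0L, ns)
  x <- array(0 + 0i, dim = c(ns, nx, ny))
  for (i in seq_len(ns)) {
    xi <- m[(i - 1L) * nx + seq_len(nx), , drop = FALSE]
    s <- shifts[i] %% ny
    if (s != 0) xi <- xi[, c((ny - s + 1):ny, 1:(ny - s)), drop = FALSE]
    x[i, , ] <- xi
  }
  x
}

c_to_2ch <- function(m) {
  out <- array(0, dim = c(nrow(m), ncol(m), 2))
  out[, , 1] <- Re(m); out[, , 2] <- Im(m)
  out
}

ch2_to_c <- function(a) {
  matrix(complex(real = a[, , 1], imaginary = a[, , 2]), dim(a)[1], dim(a)[2])
}
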