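# Unrolled variable-splitting reconstruction: alternating a learned
# regularizer (proximal surrogate) with a conjugate-gradient data-consistency
# solve of (A^H A + mu I) x = A^H y + mu z, and its backpropagation.
#
# Gradients are taken in the real vector-space sense: the gradient of a real
# loss w.r.t. a complex array v is the complex array g with
# dLoss = Re<g, dv>. The normal operator M = A^H A + mu I is Hermitian, so
# backpropagation through the CG solve x = M^{-1} b is another M-solve:
# given g_x, s = M^{-1} g_x yields g_z = mu * s and
# g_mu = Re<s, z - x>.

#' Unrolled model container
#'
#' Bundles the shared regularizer weights, the trainable quadratic-penalty
#' weight (softplus-parameterized so it stays positive), the unroll count,
#' CG settings and the operator kind the model was built/trained for.
#'
#' @param weights a [resnet_init()] weight list (shared by all unrolls).
#' @param operator_kind `"conventional"` or `"siim"`.
#' @param n_unrolls number of unrolled iterations (default 10).
#' @param cg_iters CG iterations per data-consistency solve (default 10).
#' @param mu initial penalty weight (must be positive; default 0.05).
#' @param slice_shifts optional per-slice cyclic shifts applied when
#'   concatenating slices for the regularizer.
#' @return an `unrolled_model`.
#' @export
unrolled_model <- function(weights, operator_kind = c("conventional", "siim"),
                           n_unrolls = 10L, cg_iters = 10L, mu = 0.05,
                           slice_shifts = NULL) {
  operator_kind <- match.arg(operator_kind)
  if (mu <= 0) stop("mu must be positive")
  structure(list(weights = weights, operator_kind = operator_kind,
                 n_unrolls = as.integer(n_unrolls),
                 cg_iters = as.integer(cg_iters),
                 rho = log(expm1(mu)),       # softplus^{-1}(mu)
                 slice_shifts = slice_shifts),
            class = "unrolled_model")
}

model_mu <- function(model) log1p(exp(model$rho))

# regularizer acting on a complex slice stack, with optional cache
.reg_apply <- function(x, model, keep_cache = FALSE) {
  m2 <- c_to_2ch(concat_slices(x, model$slice_shifts))
  out <- resnet_forward(m2, model$weights, keep_cache = keep_cache)
  z <- split_slices(ch2_to_c(out), dim(x)[1], model$slice_shifts)
  if (keep_cache) attr(z, "cache") <- attr(out, "cache")
  z
}

# backprop of a complex slice-stack gradient through the regularizer
.reg_backward <- function(gz, model, cache) {
  g2 <- c_to_2ch(concat_slices(gz, model$slice_shifts))
  bw <- resnet_backward(g2, model$weights, cache)
  gx <- split_slices(ch2_to_c(bw$gx), dim(gz)[1], model$slice_shifts)
  list(gx = gx, grads = bw$grads)
}

#' Unrolled forward reconstruction
#'
#' Runs `x0 = A^H y` followed by `n_unrolls` iterations of
#' `z_t = regularizer(x_{t-1})`, `x_t = argmin ||y - A x||^2 + mu ||x - z_t||^2`
#' (solved by CG). With the SIIM operator the returned series is the
#' flat-contrast solution; multiply by the intensity map
#' ([restore_intensity()]) to recover signal units.
#'
#' @param y measured k-space `(coil, readout, phase-encode)`.
#' @param op the [encoding_operator()] used for data consistency (its mask
#'   defines the DF subset).
#' @param model an [unrolled_model()].
#' @param keep_cache retain intermediates for [unrolled_backward()].
#' @return complex slice stack `(slice, x, y)`; with `keep_cache`, attribute
#'   `"cache"`.
#' @export
unrolled_forward <- function(y, op, model, keep_cache = FALSE) {
  if (model$operator_kind != op$kind)
    stop("model operator kind does not match the operator")
  mu <- model_mu(model)
  x <- op_adjoint(op, y)
  cache <- if (keep_cache) list(x0 = x, steps = vector("list", model$n_unrolls)) else NULL
  if (model$n_unrolls > 0) for (t in seq_len(model$n_unrolls)) {
    z <- .reg_apply(x, model, keep_cache = keep_cache)
    reg_cache <- attr(z, "cache")
    attr(z, "cache") <- NULL
    sol <- cg_least_squares(op, y, tol = 1e-12, max_iter = model$cg_iters,
                            mu = mu, z = z, x0 = x)
    if (keep_cache)
      cache$steps[[t]] <- list(x_prev = x, z = z, x = sol$x,
                               reg_cache = reg_cache)
    x <- sol$x
  }
  if (keep_cache) attr(x, "cache") <- cache
  x
}

# Solve M s = g with M = A^H A + mu I by CG (matrix-free); used for the
# adjoint pass through the data-consistency solve.
.solve_normal <- function(op, mu, g, iters) {
  Afun <- function(v) op_normal(op, v) + mu * v
  s <- array(0 + 0i, dim = dim(g))
  r <- g
  p <- r
  rs <- sum(Re(Conj(r) * r))
  if (rs == 0) return(s)
  for (it in seq_len(iters)) {
    Ap <- Afun(p)
    alpha <- rs / sum(Re(Conj(p) * Ap))
    s <- s + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(Re(Conj(r) * r))
    if (sqrt(rs_new) < 1e-14 * sqrt(rs)) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  s
}

#' Backpropagate a loss gradient through the unrolled reconstruction
#'
#' @param gx_out gradient of the loss w.r.t. the network-domain output
#'   (complex slice stack, real-inner-product convention).
#' @param y,op the inputs of the forward pass.
#' @param model the model used forward.
#' @param cache the `"cache"` attribute of [unrolled_forward()] output.
#' @return list with `grads` (regularizer weight gradients, summed over
#'   unrolls), `g_rho` (gradient w.r.t. the softplus parameter of mu), and
#'   `gx0` (gradient reaching the adjoint initialization).
#' @export
unrolled_backward <- function(gx_out, y, op, model, cache) {
  mu <- model_mu(model)
  g <- gx_out
  total_grads <- NULL
  g_mu <- 0
  if (model$n_unrolls > 0) for (t in rev(seq_len(model$n_unrolls))) {
    st <- cache$steps[[t]]
    s <- .solve_normal(op, mu, g, model$cg_iters)
    g_mu <- g_mu + re_inner(s, st$z - st$x)
    gz <- mu * s
    bw <- .reg_backward(gz, model, st$reg_cache)
    total_grads <- if (is.null(total_grads)) bw$grads else
      .grads_add(total_grads, bw$grads)
    g <- bw$gx
  }
  g_rho <- g_mu * stats::plogis(model$rho)     # d softplus / d rho
  list(grads = total_grads, g_rho = g_rho, gx0 = g)
}

.grads_add <- function(a, b) {
  a$w_in <- a$w_in + b$w_in; a$b_in <- a$b_in + b$b_in
  for (i in seq_along(a$blocks)) {
    a$blocks[[i]]$w1 <- a$blocks[[i]]$w1 + b$blocks[[i]]$w1
    a$blocks[[i]]$b1 <- a$blocks[[i]]$b1 + b$blocks[[i]]$b1
    a$blocks[[i]]$w2 <- a$blocks[[i]]$w2 + b$blocks[[i]]$w2
    a$blocks[[i]]$b2 <- a$blocks[[i]]$b2 + b$blocks[[i]]$b2
  }
  a$w_out <- a$w_out + b$w_out; a$b_out <- a$b_out + b$b_out
  a
}

#' Reconstruct a frame with a trained model
#'
#' Runs the unrolled network with the full acquired sampling mask as the
#' data-consistency subset (no SSDU split).
#'
#' @param y measured k-space frame.
#' @param op the [encoding_operator()] built with the frame's full mask (and
#'   intensity map for the SIIM kind).
#' @param model a trained [unrolled_model()] of matching kind.
#' @return complex slice stack (network domain; flat-contrast for SIIM).
#' @export
reconstruct_with_model <- function(y, op, model) {
  if (model$operator_kind != op$kind)
    stop("model/operator kind mismatch: model is '", model$operator_kind,
         "', operator is '", op$kind, "'")
  unrolled_forward(y, op, model, keep_cache = FALSE)
}

#' Restore signal intensity of a flat-contrast solution
#'
#' Pixelwise multiplication with the intensity map: `x_restored = L * x_siim`
#' (the unregularized identity guarantees this reproduces the conventional
#' least-squares solution; see [verify_siim_identity()]).
#'
#' @param x_siim complex slice stack `(slice, x, y)` (network domain).
#' @param L an [intensity_map()].
#' @return complex slice stack in restored signal units.
#' @export
restore_intensity <- function(x_siim, L) {
  if (!inherits(L, "intensity_map")) stop("L must be an intensity_map")
  if (any(L$values <= 0)) stop("intensity map must be floored strictly positive")
  if (length(dim(x_siim)) == 2) dim(x_siim) <- c(1L, dim(x_siim))
  stopifnot(all(dim(x_siim) == dim(L$values)))
  out <- x_siim
  for (i in seq_len(dim(out)[1])) out[i, , ] <- L$values[i, , ] * out[i, , ]
  out
}
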