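# Self-supervised (multi-mask SSDU) training of the unrolled network.
#
# Each training sample is one SMS-group k-space frame. For a sampled mask
# pair (Theta_k, Lambda_k), data consistency inside the unrolled network sees
# only Theta_k (the operator's mask is restricted, so zeroing measurements on
# Lambda_k provably cannot change the DF blocks), while the loss compares the
# full forward projection of the output on Lambda_k with the held-out
# measurements.

#' Assemble a training dataset bundle
#'
#' Convenience constructor collecting everything [train_model()] needs:
#' the acquired k-space, coil maps, sampling pattern, CAIPIRINHA schedule and
#' (for the SIIM kind) per-group/per-frame intensity maps.
#'
#' @param kspace a [kspace_sms()].
#' @param protocol the [acq_protocol()].
#' @param maps coil maps `(slice_total, coil, x, y)`.
#' @param caipi a [make_caipi_schedule()].
#' @param L_maps nested list `L_maps[[group]][[frame]]` of [intensity_map()]s
#'   (required when training the SIIM kind).
#' @param frames frame indices available for training (default: last 35 of
#'   40-style split -- frames 6..n).
#' @return a `train_dataset` list.
#' @export
train_dataset <- function(kspace, protocol, maps, caipi, L_maps = NULL,
                          frames = NULL) {
  if (is.null(frames)) {
    nf <- dim(kspace$data)[1]
    frames <- seq.int(max(1L, nf - 35L + 1L), nf)
  }
  structure(list(kspace = kspace, protocol = protocol, maps = maps,
                 caipi = caipi, L_maps = L_maps, frames = as.integer(frames)),
            class = "train_dataset")
}

# encoding operator for one group/frame of a dataset
.dataset_op <- function(dataset, group, frame, kind) {
  p <- dataset$protocol
  sms <- p$n_slices_per_group
  slices <- (group - 1L) * sms + seq_len(sms)
  maps_g <- dataset$maps[slices, , , , drop = FALSE]
  dim(maps_g) <- c(sms, p$n_coils, p$matrix_size[1], p$matrix_size[2])
  L <- NULL
  if (kind == "siim") {
    if (is.null(dataset$L_maps))
      stop("SIIM training requires precomputed intensity maps (L_maps)")
    L <- dataset$L_maps[[group]][[frame]]
  }
  encoding_operator(maps_g, dataset$kspace$pattern, dataset$caipi,
                    kind = kind, L = L)
}

#' Train the unrolled network with multi-mask SSDU
#'
#' Runs `steps` Adam updates of the shared regularizer weights and the
#' penalty scalar. Each step draws one (group, frame) sample and one SSDU
#' mask pair, reconstructs with data consistency restricted to Theta_k, and
#' scores the normalized l1-l2 loss of the predicted k-space on Lambda_k.
#' Fully deterministic given `seed`.
#'
#' @param dataset a [train_dataset()].
#' @param operator_kind `"conventional"` or `"siim"`.
#' @param config named list of hyper-parameters; recognized entries (with
#'   defaults): `n_unrolls` (10), `cg_iters` (10), `n_blocks` (15),
#'   `n_filters` (64), `steps` (100), `lr` (5e-4), `rho` (0.4), `K` (6),
#'   `mu0` (0.05), `protect_radius` (4).
#' @param seed RNG seed for initialization, sampling and mask draws.
#' @return list with `model` (trained [unrolled_model()]), `loss_trace`,
#'   `config`, `seed`.
#' @export
train_model <- function(dataset, operator_kind = c("conventional", "siim"),
                        config = list(), seed = 1L) {
  operator_kind <- match.arg(operator_kind)
  cfg <- utils::modifyList(list(n_unrolls = 10L, cg_iters = 10L,
                                n_blocks = 15L, n_filters = 64L,
                                steps = 100L, lr = 5e-4, rho = 0.4, K = 6L,
                                mu0 = 0.05, protect_radius = 4L), config)
  p <- dataset$protocol
  wt <- resnet_init(n_blocks = cfg$n_blocks, n_filters = cfg$n_filters,
                    init = "he", zero_output = TRUE, seed = seed)
  model <- unrolled_model(wt, operator_kind, n_unrolls = cfg$n_unrolls,
                          cg_iters = cfg$cg_iters, mu = cfg$mu0)
  split <- ssdu_partition(dataset$kspace$pattern, rho = cfg$rho, K = cfg$K,
                          seed = seed, protect_radius = cfg$protect_radius)
  samples <- expand.grid(group = seq_len(p$n_groups), frame = dataset$frames)
  set.seed(as.integer(seed) + 1L)
  # Adam state over (weights, rho)
  theta_v <- c(resnet_flatten(model$weights), model$rho)
  m1 <- numeric(length(theta_v)); m2 <- numeric(length(theta_v))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss_trace <- numeric(cfg$steps)
  for (step in seq_len(cfg$steps)) {
    si <- samples[sample.int(nrow(samples), 1L), ]
    k <- sample.int(split$K, 1L)
    op <- .dataset_op(dataset, si$group, si$frame, operator_kind)
    y <- dataset$kspace$data[si$frame, si$group, , , ]
    dim(y) <- c(p$n_coils, p$matrix_size[1], p$matrix_size[2])
    op_theta <- op_restrict(op, split$theta[[k]])
    op_lambda <- op_restrict(op, split$lambda[[k]])
    x <- unrolled_forward(y, op_theta, model, keep_cache = TRUE)
    cache <- attr(x, "cache"); attr(x, "cache") <- NULL
    y_pred <- op_forward(op_lambda, x)
    sel <- array(rep(split$lambda[[k]], each = p$n_coils), dim = dim(y_pred))
    ls <- ssdu_loss(y_pred[sel], y[sel], grad = TRUE)
    loss_trace[step] <- ls$loss
    gy <- array(0 + 0i, dim = dim(y_pred))
    gy[sel] <- ls$g
    gx <- op_adjoint(op_lambda, gy)
    bw <- unrolled_backward(gx, y, op_theta, model, cache)
    gvec <- c(grads_flatten(bw$grads), bw$g_rho)
    m1 <- b1 * m1 + (1 - b1) * gvec
    m2 <- b2 * m2 + (1 - b2) * gvec^2
    mh <- m1 / (1 - b1^step); vh <- m2 / (1 - b2^step)
    theta_v <- theta_v - cfg$lr * mh / (sqrt(vh) + eps)
    nwt <- length(theta_v) - 1L
    model$weights <- resnet_unflatten(theta_v[seq_len(nwt)], model$weights)
    model$rho <- theta_v[nwt + 1L]
  }
  list(model = model, loss_trace = loss_trace, config = cfg, seed = seed,
       ssdu = split)
}
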