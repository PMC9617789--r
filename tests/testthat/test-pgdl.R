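# Residual regularizer, unrolled network, SSDU splits and training.

test_that("zero-initialized network is the identity; shapes are preserved", {
  wt <- resnet_init(n_blocks = 3L, n_filters = 8L, init = "zero")
  for (dims in list(c(16L, 12L), c(9L, 21L))) {
    x <- array(rnorm(prod(dims) * 2), dim = c(dims, 2L))
    out <- resnet_forward(x, wt)
    expect_identical(dim(out), dim(x))
    expect_equal(out, x)
  }
  expect_error(resnet_forward(array(0, dim = c(4, 4, 3)), wt))
})

test_that("slice concatenation round-trips, with and without FOV shifts", {
  x <- array(rand_c(3 * 10 * 14, seed = 1), dim = c(3, 10, 14))
  m <- siimrecon:::concat_slices(x)
  expect_identical(dim(m), c(30L, 14L))
  expect_equal(siimrecon:::split_slices(m, 3L), x)
  sh <- c(0L, 5L, 9L)
  m2 <- siimrecon:::concat_slices(x, sh)
  expect_equal(siimrecon:::split_slices(m2, 3L, sh), x)
  # identity network through the concat/convert plumbing returns the stack
  wt <- resnet_init(n_blocks = 1L, n_filters = 4L, init = "zero")
  model <- unrolled_model(wt, "conventional", slice_shifts = sh)
  z <- siimrecon:::.reg_apply(x, model)
  expect_equal(z, x)
})

test_that("resnet gradients match central finite differences", {
  wt <- resnet_init(n_blocks = 2L, n_filters = 4L, init = "he", seed = 2)
  set.seed(7)
  x <- array(rnorm(8 * 6 * 2), dim = c(8, 6, 2))
  out <- resnet_forward(x, wt, keep_cache = TRUE)
  bw <- resnet_backward(array(out, dim = dim(out)), wt, attr(out, "cache"))
  v <- siimrecon:::resnet_flatten(wt)
  gv <- siimrecon:::grads_flatten(bw$grads)
  loss_at <- function(v) sum(resnet_forward(x, siimrecon:::resnet_unflatten(v, wt))^2) / 2
  set.seed(8)
  h <- 1e-5
  for (i in sample(length(v), 6)) {
    vp <- v; vp[i] <- vp[i] + h
    vm <- v; vm[i] <- vm[i] - h
    fd <- (loss_at(vp) - loss_at(vm)) / (2 * h)
    expect_lt(abs(fd - gv[i]) / max(abs(fd), 1e-10), 1e-5)
  }
})

test_that("unrolled forward: T=0 returns the adjoint; mu->0 identity regularizer approaches CG", {
  fx <- .pgdl_fixture()
  y <- array(fx$acq$kspace$data[5, 1, , , ], dim = c(fx$nc, fx$nx, fx$ny))
  wt0 <- resnet_init(n_blocks = 1L, n_filters = 4L, init = "zero")
  m0 <- unrolled_model(wt0, "conventional", n_unrolls = 0L)
  expect_equal(unrolled_forward(y, fx$op, m0), op_adjoint(fx$op, y))
  # identity regularizer, small mu, many CG iterations: close to plain CG LS
  mid <- unrolled_model(wt0, "conventional", n_unrolls = 2L, cg_iters = 80L,
                        mu = 1e-8)
  x_unroll <- unrolled_forward(y, fx$op, mid)
  x_cg <- cg_least_squares(fx$op, y, tol = 1e-12, max_iter = 200)$x
  expect_lt(relerr(x_unroll, x_cg), 1e-4)
})

test_that("unrolled loss gradients pass the finite-difference check", {
  fx <- .pgdl_fixture()
  y <- array(fx$acq$kspace$data[5, 1, , , ], dim = c(fx$nc, fx$nx, fx$ny))
  model <- unrolled_model(resnet_init(n_blocks = 2L, n_filters = 4L,
                                      init = "he", seed = 3),
                          "conventional", n_unrolls = 2L, cg_iters = 50L,
                          mu = 0.1)
  op_t <- op_restrict(fx$op, fx$split$theta[[1]])
  op_l <- op_restrict(fx$op, fx$split$lambda[[1]])
  sel <- array(rep(fx$split$lambda[[1]], each = fx$nc),
               dim = c(fx$nc, fx$nx, fx$ny))
  loss_of <- function(model) {
    x <- unrolled_forward(y, op_t, model)
    ssdu_loss(op_forward(op_l, x)[sel], y[sel])
  }
  x <- unrolled_forward(y, op_t, model, keep_cache = TRUE)
  cache <- attr(x, "cache")
  yp <- op_forward(op_l, x)
  ls <- ssdu_loss(yp[sel], y[sel], grad = TRUE)
  gy <- array(0 + 0i, dim = dim(yp)); gy[sel] <- ls$g
  bw <- unrolled_backward(op_adjoint(op_l, gy), y, op_t, model, cache)
  gv <- c(siimrecon:::grads_flatten(bw$grads), bw$g_rho)
  v <- c(siimrecon:::resnet_flatten(model$weights), model$rho)
  set.seed(9)
  idx <- c(sample(length(v) - 1L, 4), length(v))   # include the mu parameter
  h <- 1e-5
  for (i in idx) {
    vp <- v; vp[i] <- vp[i] + h
    vm <- v; vm[i] <- vm[i] - h
    mk <- function(vv) {
      m <- model
      m$weights <- siimrecon:::resnet_unflatten(vv[-length(vv)], model$weights)
      m$rho <- vv[length(vv)]
      m
    }
    fd <- (loss_of(mk(vp)) - loss_of(mk(vm))) / (2 * h)
    expect_lt(abs(fd - gv[i]) / max(abs(fd), 1e-10), 1e-3)
  }
})

test_that("gradient check also passes for the SIIM operator kind", {
  fx <- .pgdl_fixture()
  y <- array(fx$acq$kspace$data[5, 1, , , ], dim = c(fx$nc, fx$nx, fx$ny))
  Lv <- array(runif(fx$sms * fx$nx * fx$ny, 0.2, 1.2),
              dim = c(fx$sms, fx$nx, fx$ny))
  opH <- group_op(fx$ph, fx$acq, fx$proto, kind = "siim",
                  L = intensity_map(Lv))
  model <- unrolled_model(resnet_init(n_blocks = 1L, n_filters = 4L,
                                      init = "he", seed = 4),
                          "siim", n_unrolls = 2L, cg_iters = 50L, mu = 0.1)
  op_t <- op_restrict(opH, fx$split$theta[[1]])
  op_l <- op_restrict(opH, fx$split$lambda[[1]])
  sel <- array(rep(fx$split$lambda[[1]], each = fx$nc),
               dim = c(fx$nc, fx$nx, fx$ny))
  x <- unrolled_forward(y, op_t, model, keep_cache = TRUE)
  cache <- attr(x, "cache")
  yp <- op_forward(op_l, x)
  ls <- ssdu_loss(yp[sel], y[sel], grad = TRUE)
  gy <- array(0 + 0i, dim = dim(yp)); gy[sel] <- ls$g
  bw <- unrolled_backward(op_adjoint(op_l, gy), y, op_t, model, cache)
  gv <- c(siimrecon:::grads_flatten(bw$grads), bw$g_rho)
  v <- c(siimrecon:::resnet_flatten(model$weights), model$rho)
  loss_of <- function(vv) {
    m <- model
    m$weights <- siimrecon:::resnet_unflatten(vv[-length(vv)], model$weights)
    m$rho <- vv[length(vv)]
    x <- unrolled_forward(y, op_t, m)
    ssdu_loss(op_forward(op_l, x)[sel], y[sel])
  }
  set.seed(10)
  h <- 1e-5
  for (i in c(sample(length(v) - 1L, 3), length(v))) {
    vp <- v; vp[i] <- vp[i] + h
    vm <- v; vm[i] <- vm[i] - h
    fd <- (loss_of(vp) - loss_of(vm)) / (2 * h)
    expect_lt(abs(fd - gv[i]) / max(abs(fd), 1e-10), 1e-3)
  }
})

test_that("ssdu_partition: exact partition, determinism, center protection, coverage", {
  proto <- acq_protocol()   # full-size protocol mask
  pat <- make_sampling_pattern(proto)
  sp <- ssdu_partition(pat, rho = 0.4, K = 6L, seed = 3)
  for (k in 1:6) {
    expect_identical(sp$theta[[k]] | sp$lambda[[k]], pat$mask)
    expect_false(any(sp$theta[[k]] & sp$lambda[[k]]))
    frac <- sum(sp$lambda[[k]]) / sum(pat$mask)
    expect_lt(abs(frac - 0.4), 2 / sqrt(sum(pat$mask)) + 0.05)
  }
  # determinism and mask diversity
  sp2 <- ssdu_partition(pat, rho = 0.4, K = 6L, seed = 3)
  expect_identical(sp, sp2)
  expect_false(identical(sp$lambda[[1]], sp$lambda[[2]]))
  # the protected central region never leaves data consistency
  cx <- floor(proto$matrix_size[1] / 2) + 1L
  cy <- floor(proto$matrix_size[2] / 2) + 1L
  ctr <- pat$mask[cx + (-4:4), cy + (-4:4)]
  for (k in 1:6) expect_false(any(sp$lambda[[k]][cx + (-4:4), cy + (-4:4)] & ctr))
  # union coverage over K = 10 masks
  sp10 <- ssdu_partition(pat, rho = 0.4, K = 10L, seed = 4)
  un <- Reduce(`|`, sp10$lambda)
  prot <- matrix(FALSE, proto$matrix_size[1], proto$matrix_size[2])
  prot[cx + (-4:4), cy + (-4:4)] <- TRUE
  eligible <- pat$mask & !prot
  expect_gt(sum(un & eligible) / sum(eligible), 0.95)
  expect_error(ssdu_partition(pat, rho = 1e-6, K = 2L), "rho")
})

test_that("ssdu_loss: zero, scale invariance, and a hand-computed example", {
  y <- c(1 + 1i, 2 - 1i, 0.5i)
  expect_equal(ssdu_loss(y, y), 0)
  yp <- c(1 + 0.5i, 1.5 - 1i, 0.2 + 0.4i)
  a <- 0.7 - 1.3i
  expect_equal(ssdu_loss(a * yp, a * y), ssdu_loss(yp, y), tolerance = 1e-12)
  e <- y - yp
  by_hand <- sqrt(sum(Mod(e)^2)) / sqrt(sum(Mod(y)^2)) +
    sum(Mod(e)) / sum(Mod(y))
  expect_equal(ssdu_loss(yp, y), by_hand, tolerance = 1e-12)
  expect_error(ssdu_loss(complex(0), complex(0)), "empty")
  # gradient against finite differences (real and imaginary parts)
  gr <- ssdu_loss(yp, y, grad = TRUE)$g
  h <- 1e-7
  for (i in seq_along(yp)) {
    fd_re <- (ssdu_loss(yp + h * replace(numeric(3), i, 1), y) -
                ssdu_loss(yp - h * replace(numeric(3), i, 1), y)) / (2 * h)
    fd_im <- (ssdu_loss(yp + 1i * h * replace(numeric(3), i, 1), y) -
                ssdu_loss(yp - 1i * h * replace(numeric(3), i, 1), y)) / (2 * h)
    expect_lt(abs(fd_re - Re(gr[i])), 1e-6)
    expect_lt(abs(fd_im - Im(gr[i])), 1e-6)
  }
})

test_that("data-consistency blocks are provably blind to the held-out subset", {
  fx <- .pgdl_fixture()
  y <- array(fx$acq$kspace$data[4, 1, , , ], dim = c(fx$nc, fx$nx, fx$ny))
  model <- unrolled_model(resnet_init(n_blocks = 1L, n_filters = 4L,
                                      init = "he", seed = 5),
                          "conventional", n_unrolls = 2L, cg_iters = 5L)
  op_t <- op_restrict(fx$op, fx$split$theta[[2]])
  x1 <- unrolled_forward(y, op_t, model)
  y2 <- y
  for (c in seq_len(fx$nc)) {
    pl <- y2[c, , ]; pl[fx$split$lambda[[2]]] <- 0 + 0i; y2[c, , ] <- pl
  }
  expect_identical(unrolled_forward(y2, op_t, model), x1)
})

test_that("training-sample enumeration matches the protocol bookkeeping", {
  samples <- enumerate_training_samples(4L, 3L, 40L, frames_used = 35L)
  expect_equal(nrow(samples), 420L)
  expect_equal(min(samples$frame), 6L)
  expect_equal(max(samples$frame), 40L)
  expect_error(enumerate_training_samples(1L, 1L, 10L, frames_used = 11L))
})

test_that("training is deterministic and reduces the loss on a tiny phantom", {
  fx <- .pgdl_fixture()
  ds <- train_dataset(fx$acq$kspace, fx$proto, fx$ph$maps, fx$acq$caipi,
                      frames = 3:10)
  tc <- list(n_unrolls = 2L, cg_iters = 5L, n_blocks = 1L, n_filters = 6L,
             steps = 25L, lr = 2e-3, K = 3L, protect_radius = 2L)
  tr1 <- train_model(ds, "conventional", config = tc, seed = 6)
  tr2 <- train_model(ds, "conventional", config = tc, seed = 6)
  expect_identical(tr1$loss_trace, tr2$loss_trace)
  expect_lt(mean(tail(tr1$loss_trace, 5)), tr1$loss_trace[1])
  # missing intensity maps for the siim kind is an error
  expect_error(train_model(ds, "siim", config = tc, seed = 6), "intensity maps")
})

test_that("reconstruct_with_model enforces operator kind and is deterministic", {
  fx <- .pgdl_fixture()
  y <- array(fx$acq$kspace$data[3, 1, , , ], dim = c(fx$nc, fx$nx, fx$ny))
  model <- unrolled_model(resnet_init(n_blocks = 1L, n_filters = 4L,
                                      init = "he", seed = 7),
                          "conventional", n_unrolls = 1L, cg_iters = 4L)
  expect_identical(reconstruct_with_model(y, fx$op, model),
                   reconstruct_with_model(y, fx$op, model))
  Lv <- intensity_map(array(1, dim = c(fx$sms, fx$nx, fx$ny)))
  opH <- group_op(fx$ph, fx$acq, fx$proto, kind = "siim", L = Lv)
  expect_error(reconstruct_with_model(y, opH, model), "mismatch")
})

test_that("restore_intensity multiplies by L and validates flooring", {
  x <- array(rand_c(2 * 8 * 8, seed = 11), dim = c(2, 8, 8))
  L1 <- intensity_map(array(1, dim = c(2, 8, 8)))
  expect_equal(restore_intensity(x, L1), x)
  Lv <- intensity_map(array(runif(2 * 8 * 8, 0.5, 2), dim = c(2, 8, 8)))
  r1 <- restore_intensity(x, Lv)
  L2 <- Lv; L2$values <- 2 * L2$values
  expect_equal(restore_intensity(x, L2), 2 * r1)
  bad <- Lv; bad$values[1, 1, 1] <- 0
  expect_error(restore_intensity(x, bad), "floored")
  expect_error(restore_intensity(x, Lv$values), "intensity_map")
})
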