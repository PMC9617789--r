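# Sampling patterns, CAIPIRINHA schedules, and the encoding operators.

test_that("sampling pattern arithmetic matches enumeration", {
  # R=1, pf=1: everything sampled
  p1 <- small_proto(R = 1L, pf = 1)
  expect_equal(length(make_sampling_pattern(p1)$sampled_cols), 24L)
  # 160 phase-encode lines, R=4, pf=6/8, offset 0: 120-line window, 30 lines
  p2 <- acq_protocol(matrix_size = c(160L, 160L))
  expect_equal(length(make_sampling_pattern(p2)$sampled_cols), 30L)
  # lines form an arithmetic progression with step R inside the window
  pat <- make_sampling_pattern(acq_protocol(matrix_size = c(64L, 64L)))
  expect_true(all(diff(pat$sampled_cols) == 4L))
  expect_true(min(pat$sampled_cols) >= min(pat$window_cols))
  expect_error(make_sampling_pattern(small_proto(ny = 8L, R = 16L,
                                                 calib = c(4L, 4L))),
               "exceeds")
})

test_that("acceleration factor: paper protocol gives 16", {
  pat <- make_sampling_pattern(acq_protocol(matrix_size = c(160L, 160L)))
  expect_identical(acceleration_factor(pat, 3L), 16)
  p1 <- small_proto(R = 1L, pf = 1)
  expect_identical(acceleration_factor(make_sampling_pattern(p1), 1L), 1)
  p2 <- small_proto(R = 2L, pf = 1, sms = 2L)
  expect_identical(acceleration_factor(make_sampling_pattern(p2), 2L), 4)
  empty <- make_sampling_pattern(p1)
  empty$sampled_cols <- integer(0)
  expect_error(acceleration_factor(empty, 1L), "empty")
})

test_that("caipi schedule phases cycle as multiples of 2*pi*fov_shift", {
  proto <- small_proto(nx = 48L, ny = 48L, sms = 3L, R = 1L, pf = 1,
                       fs = 1 / 3, nc = 2L)
  pat <- make_sampling_pattern(proto)
  cai <- make_caipi_schedule(proto, pat)
  expect_true(all(cai$phases[1, ] == 0))
  expect_equal(cai$phases[2, 1:6],
               rep(c(0, 2 * pi / 3, 4 * pi / 3), 2), tolerance = 1e-12)
  # FFT shift theorem oracle: point object in slice 1 (0-based) moves by
  # FOV * fov_shift under full sampling
  maps <- array(1 + 0i, dim = c(3, 1, 48, 48))
  op <- encoding_operator(maps, pat, cai)
  x <- array(0 + 0i, dim = c(3, 48, 48))
  x[2, 25, 25] <- 1 + 0i                      # slice index 1 (0-based)
  y <- op_forward(op, x)
  img <- ifft2c(y[1, , ]) # contains shifted copies of all slices (here one)
  peak <- which(Mod(img) == max(Mod(img)), arr.ind = TRUE)
  shift <- as.integer((peak[2] - 25) %% 48)
  expect_true(min(shift, 48L - shift) == 16L)   # FOV/3 (direction is a convention)
})

test_that("adjoint and linearity hold across the protocol grid", {
  for (sms in c(1L, 2L, 3L)) for (R in c(1L, 2L, 4L)) for (pf in c(1, 6 / 8)) {
    proto <- small_proto(nx = 24L, ny = 24L, nc = 4L, sms = sms, R = R,
                         pf = pf, calib = c(8L, 8L))
    pat <- make_sampling_pattern(proto)
    cai <- make_caipi_schedule(proto, pat)
    maps <- random_maps(sms, 4L, 24L, 24L, seed = sms * 10 + R)
    Lv <- array(runif(sms * 24 * 24, 0.1, 2), dim = c(sms, 24, 24))
    for (kind in c("conventional", "siim")) {
      op <- encoding_operator(maps, pat, cai, kind = kind,
                              L = if (kind == "siim") intensity_map(Lv))
      x <- array(rand_c(sms * 24 * 24), dim = c(sms, 24, 24))
      y <- array(rand_c(4 * 24 * 24), dim = c(4, 24, 24))
      lhs <- sum(Conj(op_forward(op, x)) * y)
      rhs <- sum(Conj(x) * op_adjoint(op, y))
      expect_lt(Mod(lhs - rhs) / Mod(rhs), 1e-10)
      # linearity
      x2 <- array(rand_c(sms * 24 * 24), dim = c(sms, 24, 24))
      a <- 1.3 - 0.7i
      expect_lt(relerr(op_forward(op, a * x + x2),
                            a * op_forward(op, x) + op_forward(op, x2)), 1e-12)
    }
  }
})

test_that("unitary FFT conventions: Parseval and DC centering", {
  p <- small_proto(nx = 16L, ny = 16L, nc = 1L, sms = 1L, R = 1L, pf = 1,
                   calib = c(8L, 8L))
  op <- encoding_operator(array(1 + 0i, dim = c(1, 1, 16, 16)),
                          make_sampling_pattern(p))
  x <- array(rand_c(256, seed = 2), dim = c(1, 16, 16))
  y <- op_forward(op, x)
  expect_equal(sum(Mod(y)^2), sum(Mod(x)^2), tolerance = 1e-12)
  # adjoint is the inverse here
  expect_lt(relerr(op_adjoint(op, y), x), 1e-12)
  # DC centering: a constant image transforms to a single DC sample at
  # floor(N/2)+1
  k <- fft2c(matrix(1, 16, 16))
  expect_equal(which(Mod(k) > 1e-9), (9 - 1) * 16 + 9)
})

test_that("dense matrix oracle on an 8x8 grid, 2 coils, 2 slices", {
  proto <- small_proto(nx = 8L, ny = 8L, nc = 2L, sms = 2L, R = 2L,
                       pf = 1, calib = c(4L, 4L))
  pat <- make_sampling_pattern(proto)
  cai <- make_caipi_schedule(proto, pat)
  maps <- random_maps(2L, 2L, 8L, 8L, seed = 9)
  op <- encoding_operator(maps, pat, cai)
  nin <- 2 * 8 * 8; nout <- 2 * 8 * 8
  E <- matrix(0 + 0i, nout, nin)
  for (j in seq_len(nin)) {
    e <- array(0 + 0i, dim = c(2, 8, 8)); e[j] <- 1
    E[, j] <- as.vector(op_forward(op, e))
  }
  x <- array(rand_c(nin, seed = 10), dim = c(2, 8, 8))
  y <- array(rand_c(nout, seed = 11), dim = c(2, 8, 8))
  expect_lt(relerr(as.vector(op_forward(op, x)), E %*% as.vector(x)), 1e-12)
  expect_lt(relerr(as.vector(op_adjoint(op, y)),
                        Conj(t(E)) %*% as.vector(y)), 1e-12)
})

test_that("SMS forward equals the sum of single-slice forwards", {
  proto <- small_proto(nx = 16L, ny = 16L, nc = 3L, sms = 3L, R = 2L,
                       pf = 1, fs = 1 / 3, calib = c(8L, 8L))
  pat <- make_sampling_pattern(proto)
  cai <- make_caipi_schedule(proto, pat)
  maps <- random_maps(3L, 3L, 16L, 16L, seed = 3)
  op <- encoding_operator(maps, pat, cai)
  x <- array(rand_c(3 * 16 * 16, seed = 4), dim = c(3, 16, 16))
  total <- op_forward(op, x)
  acc <- array(0 + 0i, dim = dim(total))
  for (i in 1:3) {
    xi <- array(0 + 0i, dim = dim(x)); xi[i, , ] <- x[i, , ]
    acc <- acc + op_forward(op, xi)
  }
  expect_lt(relerr(acc, total), 1e-12)
})

test_that("SIIM operator properties", {
  proto <- small_proto(nx = 16L, ny = 16L, nc = 2L, sms = 2L, R = 2L, pf = 1,
                       calib = c(8L, 8L))
  pat <- make_sampling_pattern(proto)
  cai <- make_caipi_schedule(proto, pat)
  maps <- random_maps(2L, 2L, 16L, 16L, seed = 5)
  opE <- encoding_operator(maps, pat, cai)
  x <- array(rand_c(2 * 16 * 16, seed = 6), dim = c(2, 16, 16))
  # L == 1: identical to conventional
  L1 <- intensity_map(array(1, dim = c(2, 16, 16)))
  opH1 <- encoding_operator(maps, pat, cai, kind = "siim", L = L1)
  expect_identical(op_forward(opH1, x), op_forward(opE, x))
  # L == alpha: scaling
  La <- intensity_map(array(1.7, dim = c(2, 16, 16)))
  opHa <- encoding_operator(maps, pat, cai, kind = "siim", L = La)
  expect_lt(relerr(op_forward(opHa, x), 1.7 * op_forward(opE, x)), 1e-12)
  # forward_siim(x) == forward_conventional(L * x) exactly
  Lv <- array(runif(2 * 16 * 16, 0.1, 2), dim = c(2, 16, 16))
  L <- intensity_map(Lv)
  opH <- encoding_operator(maps, pat, cai, kind = "siim", L = L)
  Lx <- x
  for (i in 1:2) Lx[i, , ] <- L$values[i, , ] * x[i, , ]
  expect_identical(op_forward(opH, x), op_forward(opE, Lx))
  # negative L rejected
  expect_error(intensity_map(array(-1, dim = c(2, 4, 4))), "nonnegative")
  expect_error(encoding_operator(maps, pat, cai, kind = "siim"), "requires")
})

test_that("normal operator is Hermitian PSD; identity under full sampling", {
  proto <- small_proto(nx = 16L, ny = 16L, nc = 3L, sms = 2L, R = 2L, pf = 6 / 8,
                       calib = c(8L, 8L))
  pat <- make_sampling_pattern(proto)
  cai <- make_caipi_schedule(proto, pat)
  maps <- random_maps(2L, 3L, 16L, 16L, seed = 7)
  op <- encoding_operator(maps, pat, cai)
  x1 <- array(rand_c(2 * 16 * 16, seed = 8), dim = c(2, 16, 16))
  x2 <- array(rand_c(2 * 16 * 16, seed = 9), dim = c(2, 16, 16))
  expect_gte(Re(sum(Conj(x1) * op_normal(op, x1))), 0)
  ip12 <- sum(Conj(x1) * op_normal(op, x2))
  ip21 <- sum(Conj(x2) * op_normal(op, x1))
  expect_lt(Mod(ip12 - Conj(ip21)) / Mod(ip12), 1e-10)
  # full sampling + normalized maps + single slice: E^H E = identity
  pfull <- small_proto(nx = 16L, ny = 16L, nc = 3L, sms = 1L, R = 1L, pf = 1,
                       calib = c(8L, 8L))
  opf <- encoding_operator(random_maps(1L, 3L, 16L, 16L, seed = 10),
                           make_sampling_pattern(pfull))
  x <- array(rand_c(16 * 16, seed = 11), dim = c(1, 16, 16))
  expect_lt(relerr(op_normal(opf, x), x), 1e-12)
})

test_that("masking is idempotent", {
  proto <- small_proto(R = 2L, pf = 6 / 8)
  pat <- make_sampling_pattern(proto)
  maps <- random_maps(2L, 4L, 24L, 24L, seed = 12)
  op <- encoding_operator(maps, pat, make_caipi_schedule(proto, pat))
  x <- array(rand_c(2 * 24 * 24, seed = 13), dim = c(2, 24, 24))
  y <- op_forward(op, x)
  y2 <- y
  for (c in 1:4) y2[c, , ][!pat$mask] <- 0 + 0i
  expect_identical(y, y2)
})
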