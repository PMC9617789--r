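# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, fun) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, fun(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

rand_c <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  complex(real = rnorm(n), imaginary = rnorm(n))
}

# normalized random smooth-ish coil maps (slice, coil, nx, ny)
random_maps <- function(ns, nc, nx, ny, seed = 1) {
  set.seed(seed)
  maps <- array(rand_c(ns * nc * nx * ny), dim = c(ns, nc, nx, ny))
  ss <- sqrt(apply(Mod(maps)^2, c(1, 3, 4), sum))
  for (s in seq_len(ns)) for (c in seq_len(nc))
    maps[s, c, , ] <- maps[s, c, , ] / ss[s, , ]
  maps
}

small_proto <- function(nx = 24L, ny = 24L, nc = 4L, sms = 2L, ng = 1L,
                        nf = 4L, R = 2L, pf = 1, fs = NULL,
                        calib = c(12L, 12L)) {
  if (is.null(fs)) fs <- if (sms > 1) 1 / sms else 0
  acq_protocol(matrix_size = c(nx, ny), n_coils = nc,
               n_slices_per_group = sms, n_groups = ng, n_frames = nf,
               in_plane_R = R, partial_fourier = pf,
               fov_shift_fraction = fs, calib_size = calib)
}

# cached small phantom + noiseless acquisition used by several files
phantom_sim_48 <- function() fixture("phantom_sim_48", function() {
  proto <- small_proto(nx = 48L, ny = 48L, nc = 8L, sms = 2L, nf = 10L,
                       R = 2L, pf = 6 / 8, calib = c(24L, 24L))
  cfg <- phantom_config(matrix_size = c(48L, 48L), n_slices = 2L,
                        n_frames = 10L, n_coils = 8L, noise_sigma = 0)
  ph <- generate_phantom(cfg)
  acq <- simulate_acquisition(ph, proto, seed = 1, sigma = 0, calib_sigma = 0)
  list(proto = proto, ph = ph, acq = acq)
})

group_op <- function(ph, acq, proto, group = 1L, kind = "conventional",
                     L = NULL, use_maps = NULL) {
  sms <- proto$n_slices_per_group
  nx <- proto$matrix_size[1]; ny <- proto$matrix_size[2]
  maps <- if (is.null(use_maps)) ph$maps else use_maps
  slices <- (group - 1L) * sms + seq_len(sms)
  mg <- maps[slices, , , , drop = FALSE]
  dim(mg) <- c(sms, proto$n_coils, nx, ny)
  encoding_operator(mg, acq$pattern, acq$caipi, kind = kind, L = L)
}

relerr <- function(a, b) sqrt(sum(Mod(a - b)^2)) / sqrt(sum(Mod(b)^2))

# shared small training setup
.pgdl_fixture <- function() fixture("pgdl_fixture", function() {
  nx <- 24L; ny <- 24L; nc <- 4L; sms <- 2L
  proto <- small_proto(nx = nx, ny = ny, nc = nc, sms = sms, nf = 10L,
                       R = 2L, pf = 1, calib = c(12L, 12L))
  cfg <- phantom_config(matrix_size = c(nx, ny), n_slices = sms, n_frames = 10L,
                        n_coils = nc, noise_sigma = 0.03)
  ph <- generate_phantom(cfg)
  acq <- simulate_acquisition(ph, proto, seed = 1)
  split <- ssdu_partition(acq$pattern, rho = 0.4, K = 4L, seed = 2,
                          protect_radius = 2L)
  op <- group_op(ph, acq, proto)
  list(proto = proto, ph = ph, acq = acq, split = split, op = op,
       nx = nx, ny = ny, nc = nc, sms = sms)
})

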