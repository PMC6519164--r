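test_that("CG-SENSE inverts a fully sampled Cartesian acquisition", {
  set.seed(11)
  n <- 32
  kx <- rep(((0:(n - 1)) - n / 2) / n, n)
  ky <- rep(((0:(n - 1)) - n / 2) / n, each = n)
  coils <- simulate_coil_maps(1, n)
  img <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n)
  kd <- nufft_forward(img, cbind(kx, ky))
  rec <- cg_sense(matrix(kd, ncol = 1), cbind(kx, ky), 1, coils, max_iter = 15)
  expect_lt(max(Mod(rec - img)) / max(Mod(img)), 1e-6)
  expect_true(all(diff(attr(rec, "resnorm")) <= 1e-12))
  expect_error(cg_sense(matrix(complex(0), 0, 1), cbind(numeric(0), numeric(0)),
                        1, coils), "empty")
})

test_that("CG-SENSE converges to the dense weighted least-squares solution", {
  set.seed(5)
  n <- 8
  traj <- golden_radial(20, 8, n)
  coils <- simulate_coil_maps(2, n)
  kx <- as.vector(traj$coords[, 1, ]); ky <- as.vector(traj$coords[, 2, ])
  dcf <- as.vector(voronoi_dcf(traj))
  A <- dense_dft_matrix(cbind(kx, ky), n)
  E <- rbind(A %*% diag(as.vector(coils$maps[, , 1])),
             A %*% diag(as.vector(coils$maps[, , 2])))
  img <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n)
  k <- E %*% as.vector(img)
  sw <- sqrt(rep(dcf, 2))
  xls <- qr.solve(E * sw, k * sw)
  rec <- cg_sense(matrix(k, ncol = 2), cbind(kx, ky), dcf, coils,
                  max_iter = 200, tol = 1e-10)
  expect_lt(rel_err(as.vector(rec), xls), 1e-3)
})

test_that("CG-SENSE is linear on a well-conditioned system", {
  set.seed(2)
  n <- 16
  kx <- rep(((0:(n - 1)) - n / 2) / n, n)
  ky <- rep(((0:(n - 1)) - n / 2) / n, each = n)
  coils <- simulate_coil_maps(2, n)
  co <- cbind(kx, ky)
  mk <- function() {
    x <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n)
    v1 <- nufft_forward(x * coils$maps[, , 1], co)
    v2 <- nufft_forward(x * coils$maps[, , 2], co)
    cbind(v1, v2)
  }
  k1 <- mk(); k2 <- mk()
  a <- 1.7 - 0.4i; b <- -0.6 + 1.1i
  r1 <- cg_sense(k1, co, 1, coils, max_iter = 15)
  r2 <- cg_sense(k2, co, 1, coils, max_iter = 15)
  r12 <- cg_sense(a * k1 + b * k2, co, 1, coils, max_iter = 15)
  expect_lt(rel_err(r12, a * r1 + b * r2), 1e-6)
})

test_that("sliding-window series tile the train as configured", {
  s <- fix_sim_small()
  # window = Nt: one image from all spokes, equal to a direct cg_sense
  sw1 <- sliding_window_series(s$kdata, window = 300, stride = 1)
  expect_equal(dim(sw1$images)[3], 1)
  direct <- cg_sense(flatten_kdata(s$kdata), all_coords(s$traj),
                     as.vector(voronoi_dcf(s$traj)), s$coils)
  expect_lt(rel_err(sw1$images[, , 1], direct), 1e-12)
  expect_equal(sw1$window_center_timepoint, 151L)

  # stride = window: non-overlapping tiling
  sw2 <- sliding_window_series(s$kdata, window = 50, stride = 50)
  expect_equal(dim(sw2$images)[3], 6)
  expect_error(sliding_window_series(s$kdata, window = 400), "window")
})

test_that("low-rank inversion recovers an object inside its subspace", {
  set.seed(8)
  n <- 16; nt <- 4
  u <- complex(real = rnorm(nt), imaginary = rnorm(nt))
  u <- u / sqrt(sum(Mod(u)^2))
  obj <- matrix(0i, n, n)
  obj[5:12, 6:11] <- 1 + 0.3i
  # fully sampled Cartesian readout at every time point
  kx <- rep(((0:(n - 1)) - n / 2) / n, n)
  ky <- rep(((0:(n - 1)) - n / 2) / n, each = n)
  traj <- structure(list(coords = array(rep(c(kx, ky), nt),
                                        dim = c(n^2, 2, nt)),
                         angles = rep(0, nt), radii = kx, dr = 1 / n,
                         matrix = n, n_samples = as.integer(n^2),
                         n_timepoints = as.integer(nt)),
                    class = "radial_trajectory")
  coils <- simulate_coil_maps(2, n)
  samples <- array(0i, dim = c(n^2, 2, nt))
  for (tn in seq_len(nt)) {
    for (cc in 1:2)
      samples[, cc, tn] <- u[tn] *
        nufft_forward(obj * coils$maps[, , cc], cbind(kx, ky))
  }
  kd <- kspace_data(samples, traj, coils)
  sing <- low_rank_inversion(kd, matrix(u, ncol = 1),
                             dcf = matrix(1, n^2, nt), max_iter = 30,
                             tol = 1e-12)
  expect_lt(rel_err(sing$coeffs[, , 1], obj), 1e-4)
  expect_error(low_rank_inversion(kd, matrix(u[1:2], ncol = 1)), "basis rows")
})

test_that("low-rank inversion matches the dense least-squares solution", {
  set.seed(5)
  n <- 8; nt <- 48; R <- 3
  seqp <- fix_seq_short(nt)
  dict <- build_dictionary(c(300, 800, 1400), c(40, 80, 120), seqp,
                           slice_profile(1))
  cd <- compress_dictionary(dict, R)
  traj <- golden_radial(nt, 8, n)
  coils <- simulate_coil_maps(2, n)
  maps <- vial_phantom(n, 16, c(300, 800), c(40, 80))
  kd <- simulate_mrf_kspace(maps, seqp, dict, traj, coils, NULL)
  dcf <- voronoi_dcf(traj)
  rows <- vector("list", nt * 2)
  kvec <- complex(0)
  xc <- rep((0:(n - 1)) - n / 2, n); yc <- rep((0:(n - 1)) - n / 2, each = n)
  i <- 1
  for (tn in seq_len(nt)) {
    Atn <- dense_dft_matrix(cbind(traj$coords[, 1, tn], traj$coords[, 2, tn]), n)
    for (cc in 1:2) {
      blk <- do.call(cbind, lapply(seq_len(R), function(r)
        cd$basis[tn, r] * (Atn %*% diag(as.vector(coils$maps[, , cc])))))
      rows[[i]] <- blk * sqrt(dcf[, tn]); i <- i + 1
      kvec <- c(kvec, kd$samples[, cc, tn] * sqrt(dcf[, tn]))
    }
  }
  xls <- qr.solve(do.call(rbind, rows), kvec)
  sing <- low_rank_inversion(kd, cd, max_iter = 400, tol = 1e-12)
  expect_lt(rel_err(as.vector(sing$coeffs), xls), 1e-3)

  # linearity at a fixed iteration budget on consistent data
  s1 <- low_rank_inversion(kd, cd, max_iter = 15)
  kd2 <- kd; kd2$samples <- 2i * kd$samples
  s2 <- low_rank_inversion(kd2, cd, max_iter = 15)
  expect_lt(rel_err(s2$coeffs, 2i * s1$coeffs), 1e-6)

  # time-series projection is the basis expansion
  ts <- project_timeseries(s1, timepoints = c(1, 10))
  byhand <- matrix(s1$coeffs, n * n, R) %*% t(cd$basis[c(1, 10), ])
  expect_equal(as.vector(ts), as.vector(byhand))
})
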