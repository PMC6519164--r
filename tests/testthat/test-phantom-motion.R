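test_that("digital phantoms carry the configured tissue values", {
  bp <- brain_phantom(96, 320)
  wm <- bp$t1_ms == 738
  expect_true(any(wm))
  expect_true(all(bp$t2_ms[wm] == 48))
  gm <- bp$t1_ms == 1127
  expect_true(all(bp$t2_ms[gm] == 69))
  expect_true(all(bp$m0[!bp$mask] == 0))
  expect_true(all(bp$t1_ms[bp$mask] > 0 & bp$t2_ms[bp$mask] > 0))
  expect_identical(bp, brain_phantom(96, 320))       # deterministic
  expect_error(brain_phantom(16, 320), "matrix")

  vp <- vial_phantom(64, 320, c(200, 600, 1000), c(40, 90, 150))
  for (v in 1:3) {
    sel <- vp$t1_ms == c(200, 600, 1000)[v]
    expect_true(any(sel))
    expect_true(all(vp$t2_ms[sel] == c(40, 90, 150)[v]))
  }
  expect_error(vial_phantom(64, 320, numeric(0), numeric(0)), "non-empty")
})

test_that("motion generators reproduce the printed simulation shapes", {
  # simulation (1): step at time point 250 of 1750, 8 px / 2 px / 12 deg
  m1 <- motion_abrupt(1750, 250, 8, 2, 12, pixel_mm = 2)
  expect_equal(m1$tx_mm[1:250], rep(0, 250))
  expect_equal(unique(m1$tx_mm[251:1750]), 16)       # 8 px at 2 mm
  expect_equal(unique(m1$ty_mm[251:1750]), 4)
  expect_equal(unique(m1$theta_deg[251:1750]), 12)
  # simulation (2) variant: same step later in the train
  m2 <- motion_abrupt(1750, 1500, 8, 2, 12, pixel_mm = 2)
  expect_equal(sum(m2$theta_deg != 0), 250)
  # null amplitudes give the identity trajectory
  m0 <- motion_abrupt(100, 50, 0, 0, 0, pixel_mm = 2)
  expect_true(all(c(m0$tx_mm, m0$ty_mm, m0$theta_deg) == 0))

  # simulation (3): peak amplitudes, n_cycles full periods
  m3 <- motion_sinusoidal(1750, 8, 2, 24, n_cycles = 3, pixel_mm = 2)
  expect_equal(max(abs(m3$theta_deg)), 24, tolerance = 1e-3)
  expect_equal(max(abs(m3$tx_mm)), 16, tolerance = 1e-2)
  expect_true(all(motion_sinusoidal(100, 8, 2, 24, 0, 2)$theta_deg == 0))
})

test_that("rigid image transform is exact where it should be", {
  set.seed(3)
  xg <- matrix(rep(1:64, 64), 64) - 30
  yg <- t(matrix(rep(1:64, 64), 64)) - 36
  img <- exp(-(xg^2 + yg^2) / (2 * 8^2)) +
    0.5 * exp(-((xg - 10)^2 + (yg + 8)^2) / (2 * 5^2))
  sm <- apply_rigid(img, 0, 0, 0)
  expect_equal(sm, img)                              # identity

  sh <- apply_rigid(img, 6, -4, 0)                   # integer shift, pixel_mm 1
  expect_equal(sh[27:46, 22:41], img[21:40, 26:45])

  fw <- apply_rigid(img, 3.3, -2.1, 17, pixel_mm = 1)
  th <- 17 * pi / 180
  bk <- apply_rigid(fw, -(cos(th) * 3.3 + sin(th) * -2.1),
                    -(-sin(th) * 3.3 + cos(th) * -2.1), -17, pixel_mm = 1)
  expect_lt(sqrt(mean((bk - img)^2)) / sqrt(mean(img^2)), 0.02)
})

test_that("simulated k-space matches an FFT on full Cartesian sampling", {
  n <- 32
  seqp <- sequence_params(30, invert = FALSE)
  maps <- brain_phantom(n, 320)
  coils <- simulate_coil_maps(2, n)
  kx <- rep(((0:(n - 1)) - n / 2) / n, n)
  ky <- rep(((0:(n - 1)) - n / 2) / n, each = n)
  traj <- structure(list(coords = array(c(kx, ky), dim = c(n^2, 2, 1)),
                         angles = 0, radii = kx, dr = 1 / n, matrix = n,
                         n_samples = as.integer(n^2), n_timepoints = 1L),
                    class = "radial_trajectory")
  kd <- simulate_mrf_kspace(maps, seqp, NULL, traj, coils,
                            profile = slice_profile(1))
  # per-class contrast image
  key <- paste(maps$t1_ms, maps$t2_ms)
  classes <- unique(key[maps$mask])
  contrast <- matrix(0i, n, n)
  for (k in classes) {
    tv <- as.numeric(strsplit(sub(" ", "/", k), "/")[[1]])
    f <- epg_fisp_signal(tv[1], tv[2], seqp)
    contrast[key == k & maps$mask] <- maps$m0[key == k & maps$mask] * f[1]
  }
  for (cc in 1:2) {
    grid <- matrix(kd$samples[, cc, 1], n, n)
    # invert the centred DFT by FFT with explicit phase bookkeeping
    rec <- Conj(t(dense_dft_matrix(cbind(kx, ky), n))) %*%
      as.vector(grid) / n^2
    expect_lt(rel_err(matrix(rec, n, n), contrast * coils$maps[, , cc]), 1e-5)
  }
})

test_that("translation obeys the Fourier shift theorem on every spoke", {
  s <- fix_sim_small()
  nt <- 300
  mo <- rigid_motion(rep(6.5 * s$maps$pixel_mm, nt),
                     rep(2.3 * s$maps$pixel_mm, nt), rep(0, nt))
  kdm <- simulate_mrf_kspace(s$maps, s$seq, s$dict, s$traj, s$coils, mo)
  for (n in c(5, 57, 150, 300)) {   # spoke 1 has zero flip angle (no signal)
    ref <- s$kdata$samples[, 1, n]
    sig <- Mod(ref) > 0.02 * max(Mod(ref))
    ratio <- kdm$samples[sig, 1, n] / ref[sig]
    expect_lt(max(abs(Mod(ratio) - 1)), 1e-3)
    pred <- exp(-2i * pi * (s$traj$coords[sig, 1, n] * 6.5 +
                              s$traj$coords[sig, 2, n] * 2.3))
    expect_lt(max(Mod(ratio - pred)), 1e-3)
  }
})

test_that("simulation is reproducible and validates its inputs", {
  s <- fix_sim_small()
  kd2 <- simulate_mrf_kspace(s$maps, s$seq, s$dict, s$traj, s$coils, NULL)
  expect_identical(s$kdata$samples, kd2$samples)

  kn1 <- simulate_mrf_kspace(s$maps, s$seq, s$dict, s$traj, s$coils, NULL,
                             noise_sd = 0.1, seed = 9)
  kn2 <- simulate_mrf_kspace(s$maps, s$seq, s$dict, s$traj, s$coils, NULL,
                             noise_sd = 0.1, seed = 9)
  expect_identical(kn1$samples, kn2$samples)
  expect_false(identical(kn1$samples, s$kdata$samples))

  # the simulator demands exact fingerprint lookup
  bad <- brain_phantom(64, 320, wm = c(739, 48))
  expect_error(simulate_mrf_kspace(bad, s$seq, s$dict, s$traj, s$coils, NULL),
               "lacks fingerprints")
})

test_that("spoke energy is conserved under rotation of a round phantom", {
  n <- 64
  seqp <- sequence_params(rep(30, 30), invert = FALSE)
  # radially symmetric smooth object: a centred Gaussian density blob
  # (a binary vial's pixelized edge is not exactly rotation-symmetric)
  xg <- matrix(rep(0:(n - 1), n), n) - n / 2
  rg2 <- xg^2 + t(xg)^2
  m0 <- exp(-rg2 / (2 * 9^2))
  vp <- tissue_maps(matrix(800, n, n), matrix(80, n, n), m0,
                    m0 > 1e-8, fov_mm = 320)
  traj <- golden_radial(30, 64, n)
  coils <- simulate_coil_maps(1, n)
  kd0 <- simulate_mrf_kspace(vp, seqp, NULL, traj, coils, NULL,
                             profile = slice_profile(1))
  mo <- rigid_motion(rep(0, 30), rep(0, 30), rep(25, 30))
  kdr <- simulate_mrf_kspace(vp, seqp, NULL, traj, coils, mo,
                             profile = slice_profile(1))
  e0 <- colSums(Mod(kd0$samples[, 1, ])^2)
  er <- colSums(Mod(kdr$samples[, 1, ])^2)
  expect_lt(max(abs(er / e0 - 1)), 1e-3)
})
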