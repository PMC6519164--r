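test_that("NMI behaves like a normalized mutual information should", {
  set.seed(21)
  a <- matrix(runif(128^2), 128)
  b <- matrix(runif(128^2), 128)
  expect_equal(nmi(a, a), 2, tolerance = 1e-6)
  expect_lt(nmi(a, b), 1.05)            # independence limit
  expect_gte(nmi(a, b), 1)
  expect_equal(nmi(a, 2 * a + 1), nmi(a, a))  # monotone remap invariance
  expect_warning(v <- nmi(matrix(1, 8, 8), a[1:8, 1:8]), "constant")
  expect_equal(v, 1)
  expect_error(nmi(a, b[1:64, 1:64]), "shape")
})

test_that("rigid registration recovers synthetic poses to sub-pixel accuracy", {
  maps <- brain_phantom(128, 320)
  img <- Mod(maps$m0) * maps$t2_ms / 100 + 0.2 * Mod(maps$m0)
  px <- maps$pixel_mm

  idt <- register_rigid(img, img, pixel_mm = px)
  expect_lt(abs(idt$tx_mm) / px, 0.1)
  expect_lt(abs(idt$ty_mm) / px, 0.1)
  expect_lt(abs(idt$theta_deg), 0.1)

  # known pose: moving = apply_rigid(fixed, 16 mm, 4 mm, 12 deg); the
  # registration output is the inverse pose
  mov <- apply_rigid(img, 16, 4, 12, pixel_mm = px)
  tr <- register_rigid(mov, img, pixel_mm = px)
  th <- 12 * pi / 180
  exp_tx <- -(cos(th) * 16 + sin(th) * 4)
  exp_ty <- -(-sin(th) * 16 + cos(th) * 4)
  expect_lt(abs(tr$tx_mm - exp_tx) / px, 0.5)
  expect_lt(abs(tr$ty_mm - exp_ty) / px, 0.5)
  expect_lt(abs(tr$theta_deg - (-12)), 0.5)

  # invariant to global intensity scaling of either image
  tr2 <- register_rigid(3.7 * mov, img, pixel_mm = px)
  expect_equal(tr2$tx_mm, tr$tx_mm, tolerance = 1e-8)
  expect_equal(tr2$theta_deg, tr$theta_deg, tolerance = 1e-8)
})

test_that("multi-reference estimation recovers a known step trajectory", {
  maps <- brain_phantom(96, 320)
  img <- Mod(maps$m0) * maps$t1_ms / 1000
  nw <- 24
  poses <- cbind(tx = c(rep(0, 10), rep(5, 14)),
                 ty = c(rep(0, 10), rep(2, 14)),
                 th = c(rep(0, 10), rep(8, 14)))
  images <- array(0i, dim = c(96, 96, nw))
  for (w in seq_len(nw))
    images[, , w] <- apply_rigid(img, poses[w, 1], poses[w, 2], poses[w, 3],
                                 pixel_mm = 1)
  series <- structure(list(images = images,
                           window_center_timepoint = seq(10, by = 10,
                                                         length.out = nw),
                           window = 20L, stride = 10L),
                      class = "sliding_window_series")
  est <- estimate_motion_multireference(series, reference_stride = 12,
                                        n_timepoints = 240, pixel_mm = 1)
  # zero mean per parameter, by construction
  expect_equal(mean(est$tx_mm), 0, tolerance = 1e-10)
  expect_equal(mean(est$ty_mm), 0, tolerance = 1e-10)
  expect_equal(mean(est$theta_deg), 0, tolerance = 1e-10)
  # recovered trajectory equals the centred truth away from the step
  truth <- interpolate_motion(rigid_motion(poses[, 1], poses[, 2], poses[, 3]),
                              series$window_center_timepoint, 240)
  ctr <- function(x) x - mean(x)
  away <- c(1:80, 130:240)
  expect_lt(max(abs(est$tx_mm - ctr(truth$tx_mm))[away]), 0.5)
  expect_lt(max(abs(est$ty_mm - ctr(truth$ty_mm))[away]), 0.5)
  expect_lt(max(abs(est$theta_deg - ctr(truth$theta_deg))[away]), 0.5)

  # halving the number of references moves the result by less than the
  # tolerance above
  est2 <- estimate_motion_multireference(series, reference_stride = 24,
                                         n_timepoints = 240, pixel_mm = 1)
  expect_lt(max(abs(est$theta_deg - est2$theta_deg)), 0.5)

  # a single window yields the null trajectory
  one <- series; one$images <- series$images[, , 1, drop = FALSE]
  z <- estimate_motion_multireference(one, n_timepoints = 50)
  expect_true(all(c(z$tx_mm, z$ty_mm, z$theta_deg) == 0))
})

test_that("static sliding-window images yield a null motion estimate", {
  s <- fix_sim_small()
  sw <- sliding_window_series(s$kdata, window = 50, stride = 20)
  est <- estimate_motion_multireference(sw, reference_stride = 100,
                                        n_timepoints = 300,
                                        pixel_mm = s$maps$pixel_mm)
  expect_lt(max(abs(est$tx_mm)) / s$maps$pixel_mm, 0.5)
  expect_lt(max(abs(est$ty_mm)) / s$maps$pixel_mm, 0.5)
  expect_lt(max(abs(est$theta_deg)), 0.5)
})
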