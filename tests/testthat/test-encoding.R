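test_that("golden-angle trajectory has the canonical geometry", {
  tr <- golden_radial(50, 32, 32)
  # spoke 0 is horizontal; increments equal the golden angle mod pi
  expect_equal(tr$angles[1], 0)
  expect_equal(golden_angle() * 180 / pi, 111.2461, tolerance = 1e-4)
  d <- diff((seq_len(50) - 1) * golden_angle()) %% pi
  expect_true(all(abs(d - d[1]) < 1e-12))
  expect_equal((tr$angles[2] - tr$angles[1]) %% pi, golden_angle() %% pi)
  # samples span the Nyquist extent through DC
  expect_true(all(abs(tr$coords) <= 0.5))
  expect_equal(tr$radii, ((0:31) - 16) / 32)
})

test_that("Voronoi weights recover the analytic radial limits", {
  # many uniformly distributed spokes: interior weights proportional to |k|
  tr <- golden_radial(100, 64, 64)
  tr$angles <- (0:99) * pi / 100
  w <- voronoi_dcf(tr)
  r <- abs(tr$radii)
  int <- r > 0.05 & r < 0.45
  ratio <- w[int, 1] / r[int]
  expect_lt(max(abs(ratio / mean(ratio) - 1)), 0.05)
  # normalization: total weight equals the sampled disk area
  disk <- pi * (max(abs(tr$radii)) + tr$dr / 2)^2
  expect_equal(sum(w), disk, tolerance = 1e-10)

  # two orthogonal spokes: weights symmetric under the 90 degree swap
  t2 <- golden_radial(2, 32, 32); t2$angles <- c(0, pi / 2)
  w2 <- voronoi_dcf(t2)
  expect_equal(w2[, 1], w2[, 2], tolerance = 1e-12)

  # duplicating a spoke halves each duplicate's weight
  t3 <- golden_radial(3, 32, 32); t3$angles <- c(0.3, 0.3, 1.2)
  t1 <- golden_radial(2, 32, 32); t1$angles <- c(0.3, 1.2)
  w3 <- voronoi_dcf(t3); w1 <- voronoi_dcf(t1)
  sc <- sum(w1) / sum(w3) * (3 / 2)  # same disk normalization
  expect_equal(w3[10, 1] / w1[10, 1] * sc / sc, 0.5, tolerance = 1e-6)

  # single spoke direction falls back to ramp weighting
  ts <- golden_radial(1, 32, 32)
  expect_warning(ws <- voronoi_dcf(ts), "ramp")
  rr <- abs(ts$radii)
  expect_equal(ws[rr > 0, 1] / rr[rr > 0],
               rep(ws[2, 1] / rr[2], sum(rr > 0)), tolerance = 1e-10)
})

test_that("NUFFT agrees with the direct Fourier sum and its adjoint", {
  set.seed(7)
  n <- 16
  img <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n)
  co <- cbind(runif(50, -0.5, 0.4999), runif(50, -0.5, 0.4999))
  direct <- dense_dft_matrix(co, n) %*% as.vector(img)
  fw <- nufft_forward(img, co)
  expect_lt(max(Mod(fw - as.vector(direct))) / max(Mod(direct)), 1e-5)

  # unit impulse at the grid centre: flat unit-magnitude spectrum
  imp <- matrix(0i, n, n); imp[n / 2 + 1, n / 2 + 1] <- 1
  expect_lt(max(abs(Mod(nufft_forward(imp, co)) - 1)), 1e-5)

  # adjoint identity at several grid sizes
  for (nn in c(8, 16, 32)) {
    x <- matrix(complex(real = rnorm(nn^2), imaginary = rnorm(nn^2)), nn)
    cc <- cbind(runif(30, -0.5, 0.4999), runif(30, -0.5, 0.4999))
    y <- complex(real = rnorm(30), imaginary = rnorm(30))
    lhs <- sum(Conj(y) * nufft_forward(x, cc))
    rhs <- sum(Conj(nufft_adjoint(y, cc, nn)) * x)
    expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-5)
  }

  expect_error(nufft_forward(img, cbind(0.7, 0)), "coordinates")
})

test_that("analytic coil maps are smooth, deterministic and complete", {
  c1 <- simulate_coil_maps(1, 32)
  expect_equal(c1$maps[, , 1], matrix(1 + 0i, 32, 32))

  c8 <- simulate_coil_maps(8, 64)
  rss <- sqrt(apply(Mod(c8$maps)^2, c(1, 2), sum))
  expect_true(all(rss > 0))
  # smoothness: neighbouring pixels differ by little
  expect_lt(max(abs(diff(rss))), 0.05 * max(rss))
  expect_identical(c8$maps, simulate_coil_maps(8, 64)$maps)
})
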