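test_that("EPG reproduces closed-form limits", {
  # no RF, no signal
  s0 <- epg_fisp_signal(1000, 100, sequence_params(rep(0, 50)))
  expect_equal(max(Mod(s0)), 0)

  # single 90 degree pulse on fresh magnetization: |s| = exp(-TE/T2)
  s90 <- epg_fisp_signal(1000, 100, sequence_params(90, invert = FALSE))
  expect_equal(Mod(s90)[1], exp(-1.23 / 100), tolerance = 1e-12)

  # inversion recovery: FA = 0 for n TRs, then a 90 degree readout sees
  # Mz = 1 - 2 exp(-n TR / T1)
  nrec <- 120; t1 <- 800; t2 <- 100
  seqp <- sequence_params(c(rep(0, nrec), 90))
  sig <- epg_fisp_signal(t1, t2, seqp)
  mz <- 1 - 2 * exp(-nrec * seqp$tr_ms / t1)
  expect_equal(Mod(sig[nrec + 1]), abs(mz) * exp(-seqp$te_ms / t2),
               tolerance = 1e-6)
})

test_that("EPG matches an independent isochromat simulation", {
  set.seed(42)
  for (k in 1:4) {
    t1 <- runif(1, 300, 3000)
    t2 <- runif(1, 30, min(t1, 400))
    seqp <- sequence_params(mrf_flip_angle_schedule(200, n_lobes = sample(2:6, 1),
                                                    peak_deg = runif(1, 40, 70)))
    epg <- epg_fisp_signal(t1, t2, seqp)
    iso <- iso_fisp_oracle(t1, t2, seqp$flip_angles, seqp$tr_ms, seqp$te_ms,
                           TRUE, nspins = 301)
    expect_lt(max(Mod(epg - iso)) / max(Mod(iso)), 1e-3)
  }
})

test_that("EPG input validation and T2 > T1 warning behave", {
  seqp <- fix_seq_short()
  expect_error(epg_fisp_signal(-5, 50, seqp), "t1_ms")
  expect_error(epg_fisp_signal(500, 0, seqp), "t2_ms")
  expect_warning(epg_fisp_signal(100, 300, seqp), "T2")
})

test_that("slice-profile averaging equals its direct summation", {
  seqp <- fix_seq_short()
  p1 <- structure(list(positions = 0, scale = 1), class = "slice_profile")
  expect_equal(epg_with_slice_profile(900, 70, seqp, p1),
               epg_fisp_signal(900, 70, seqp))

  rect <- slice_profile(50, shape = "rect")
  expect_equal(epg_with_slice_profile(900, 70, seqp, rect),
               epg_fisp_signal(900, 70, seqp), tolerance = 1e-12)

  gau <- slice_profile(50, shape = "gaussian")
  direct <- Reduce(`+`, lapply(gau$scale, function(s)
    epg_fisp_signal(900, 70, seqp, fa_scale = s))) / 50
  expect_equal(epg_with_slice_profile(900, 70, seqp, gau), direct,
               tolerance = 1e-12)

  expect_equal(max(slice_profile(50)$scale), 1)
  expect_error(epg_with_slice_profile(900, 70, seqp, list()), "slice_profile")
})

test_that("segmented grid parsing follows inclusive start:step:stop semantics", {
  expect_equal(parse_grid(list(c(0, 30, 200))), seq(0, 180, by = 30))
  expect_equal(parse_grid(list(c(100, 50, 100))), 100)

  # brute-force enumeration oracle for the published phantom T2 grid
  spec <- list(c(0, 2, 70), c(70, 10, 120), c(120, 5, 270))
  brute <- sort(unique(c(seq(0, 70, 2), seq(70, 120, 10), seq(120, 270, 5))))
  expect_equal(parse_grid(spec), brute)

  expect_error(parse_grid(list(c(10, 5, 5))), "stop")
  expect_error(parse_grid(list(c(0, -1, 10))), "step")
})

test_that("dictionary construction is deterministic and exact per atom", {
  seqp <- fix_seq_short()
  prof <- slice_profile(5)
  expect_message(d1 <- build_dictionary(c(0, 500), c(0, 50), seqp, prof),
                 "zero")
  expect_equal(ncol(d1$atoms), 1)
  expect_equal(as.vector(d1$atoms[, 1]),
               epg_with_slice_profile(500, 50, seqp, prof))

  # duplicate grid entries collapse; ordering is T1-major, T2-minor
  d2 <- build_dictionary(c(300, 300, 800), c(40, 90), seqp, prof)
  expect_equal(nrow(d2$entries), 4)
  expect_equal(d2$entries$t1_ms, c(300, 300, 800, 800))
  expect_equal(d2$entries$t2_ms, c(40, 90, 40, 90))

  # T2 > T1 exclusion switch prunes the product
  d3 <- build_dictionary(c(50, 800), c(40, 90), seqp, prof,
                         exclude_t2_gt_t1 = TRUE)
  expect_equal(nrow(d3$entries), 3)

  # atom count equals independent enumeration of the deduplicated product
  t1g <- parse_grid(list(c(200, 100, 600)))
  t2g <- parse_grid(list(c(20, 20, 100)))
  d4 <- build_dictionary(t1g, t2g, seqp, prof)
  expect_equal(ncol(d4$atoms), length(unique(t1g)) * length(unique(t2g)))
})

test_that("SVD compression captures energy as an independent SVD says", {
  seqp <- fix_seq_short()
  dict <- build_dictionary(seq(300, 1500, by = 200), seq(30, 150, by = 20),
                           seqp, slice_profile(3))
  nt <- nrow(dict$atoms)

  cd_full <- compress_dictionary(dict, min(nt, ncol(dict$atoms)))
  resid <- dict$atoms - cd_full$basis %*% (Conj(t(cd_full$basis)) %*% dict$atoms)
  expect_lt(sqrt(sum(Mod(resid)^2)), 1e-8 * sqrt(sum(Mod(dict$atoms)^2)))

  cd <- compress_dictionary(dict, 4)
  expect_equal(Conj(t(cd$basis)) %*% cd$basis, diag(4) + 0i, tolerance = 1e-10)
  sv <- svd(dict$atoms)$d                        # independent SVD oracle
  expect_equal(cd$energy_fraction, sum(sv[1:4]^2) / sum(sv^2), tolerance = 1e-8)
  expect_equal(cd$compressed_atoms, Conj(t(cd$basis)) %*% dict$atoms)

  # projection residual is monotonically non-increasing in rank
  res_r <- vapply(1:6, function(r) {
    cdr <- compress_dictionary(dict, r)
    sqrt(sum(Mod(dict$atoms - cdr$basis %*% cdr$compressed_atoms)^2))
  }, 0)
  expect_true(all(diff(res_r) <= 1e-8))

  # rank-1 family of proportional atoms is captured exactly by R = 1
  base <- epg_fisp_signal(700, 60, seqp)
  d1 <- build_dictionary(700, 60, seqp, slice_profile(1))
  d1$atoms <- cbind(base, 2 * base, 0.5 * base)
  d1$entries <- data.frame(t1_ms = c(700, 701, 702), t2_ms = 60)
  d1$atom_norms <- sqrt(colSums(Mod(d1$atoms)^2))
  c1 <- compress_dictionary(d1, 1)
  expect_lt(sqrt(sum(Mod(d1$atoms - c1$basis %*% c1$compressed_atoms)^2)), 1e-8)

  expect_error(compress_dictionary(dict, 0), "rank")
})
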