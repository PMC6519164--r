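#' Normalized mutual information of two images
#'
#' \code{NMI = (H(A) + H(B)) / H(A, B)} from a joint histogram with linear
#' binning between each image's min and max, computed over the pixels where
#' both images are finite (the intersection mask). Ranges from 1
#' (independent) to 2 (identical up to a monotone intensity remapping at
#' matched binning). A constant image yields 1, with a warning.
#'
#' @param img_a,img_b numeric matrices of the same size (magnitudes).
#' @param bins histogram bins per image.
#' @return NMI in \code{[1, 2]}.
#' @export
nmi <- function(img_a, img_b, bins = 32) {
  if (!all(dim(img_a) == dim(img_b))) stopf("images must have the same shape")
  v <- cpp_nmi(img_a, img_b, as.integer(bins))
  if (v == 1 && (max(img_a) == min(img_a) || max(img_b) == min(img_b)))
    warning("constant image; NMI undefined, returning 1")
  v
}

downsample2 <- function(img, f) {
  if (f == 1) return(img)
  n <- nrow(img)
  m <- (n %/% f) * f
  img <- img[seq_len(m), seq_len(m)]
  blk <- array(img, dim = c(f, m / f, f, m / f))
  apply(blk, c(2, 4), mean)
}

#' Rigid registration by NMI maximization
#'
#' Estimates the rigid transform (tx, ty, theta) that maps \code{moving}
#' onto \code{fixed} by maximizing normalized mutual information. A
#' coarse-to-fine pyramid is used: exhaustive seeding over translations
#' (+-\code{coarse_frac} of the FOV) and rotations (+-\code{theta_range_deg})
#' at the coarse level, a local grid refinement at the intermediate level,
#' and Nelder-Mead polish at full resolution. NMI makes the result
#' invariant to global intensity scaling of either image.
#'
#' @param moving,fixed numeric matrices (magnitude images, same geometry).
#' @param bins NMI histogram bins.
#' @param theta_range_deg rotation search range, degrees.
#' @param coarse_frac translation search range as a fraction of the FOV.
#' @param pixel_mm pixel size used to report translations in mm.
#' @return A list (class \code{rigid_transform}) with \code{tx_mm},
#'   \code{ty_mm}, \code{theta_deg}, \code{nmi}.
#' @export
register_rigid <- function(moving, fixed, bins = 32, theta_range_deg = 30,
                           coarse_frac = 0.25, pixel_mm = 1) {
  if (!all(dim(moving) == dim(fixed))) stopf("images must have the same geometry")
  moving <- abs(moving); fixed <- abs(fixed)
  n <- nrow(fixed)
  f1 <- max(1, round(n / 32))          # coarse level ~32 px
  f2 <- max(1, round(n / 64))          # intermediate level ~64 px
  fx1 <- downsample2(fixed, f1); mv1 <- downsample2(moving, f1)
  tr_range <- coarse_frac * n
  dth <- 0.007                          # off-grid dither pose (see C++ docs)
  txs <- seq(-tr_range, tr_range, by = 4) / f1
  ths <- seq(-theta_range_deg, theta_range_deg, by = 3) * pi / 180
  seed <- cpp_register_grid(fx1, mv1, txs, txs, ths, 0.5, 0.5, dth,
                            as.integer(bins))
  best <- c(seed[1] * f1, seed[2] * f1, seed[3])

  if (f2 < f1) {
    fx2 <- downsample2(fixed, f2); mv2 <- downsample2(moving, f2)
    loc_t <- (best[1] + seq(-4, 4, by = 1)) / f2
    loc_u <- (best[2] + seq(-4, 4, by = 1)) / f2
    loc_h <- best[3] + seq(-3, 3, by = 1) * pi / 180
    ref <- cpp_register_grid(fx2, mv2, loc_t, loc_u, loc_h, 0.5, 0.5, dth,
                             as.integer(bins))
    best <- c(ref[1] * f2, ref[2] * f2, ref[3])
  }

  fixed_d <- cpp_transform_masked(fixed, 0.5, 0.5, dth)
  obj <- function(p) -cpp_nmi_dithered(fixed_d, moving, p[1], p[2], p[3],
                                       0.5, 0.5, dth, as.integer(bins))
  opt <- optim(best, obj, method = "Nelder-Mead",
               control = list(maxit = 300, reltol = 1e-10,
                              parscale = c(1, 1, 0.02)))
  if (-opt$value < -obj(best)) opt <- list(par = best, value = obj(best))
  structure(list(tx_mm = opt$par[1] * pixel_mm, ty_mm = opt$par[2] * pixel_mm,
                 theta_deg = opt$par[3] * 180 / pi, nmi = -opt$value),
            class = "rigid_transform")
}

#' Multi-reference motion estimation from sliding-window images
#'
#' Registers every intermediate image to each of a set of reference images
#' (every \code{reference_stride}-th window), inverts the registration
#' transforms into object poses, brings all references into a common frame
#' by exact pose composition (robust to individual failed registrations),
#' averages, and interpolates from the window centres to every time point
#' (linear, constant extrapolation at the ends). The repeated registration
#' to references spread over the scan suppresses errors caused by the
#' varying signal contrast. The result is reported in the mean-pose frame:
#' each parameter has zero mean by construction, and the subtracted means
#' are stored as attribute \code{"gauge_offset"} so that
#' [correct_kspace()] can restore a self-consistent pose sequence.
#'
#' @param series a [sliding_window_series()] object.
#' @param reference_stride spacing of reference windows (in windows).
#' @param n_timepoints trajectory length to interpolate to (default: last
#'   window centre).
#' @param pixel_mm pixel size in mm.
#' @param bins,theta_range_deg passed to [register_rigid()].
#' @return A [rigid_motion()] of length \code{n_timepoints}; per-window
#'   estimates are attached as attribute \code{"window_estimates"}.
#' @export
estimate_motion_multireference <- function(series, reference_stride = 100,
                                           n_timepoints = NULL, pixel_mm = 1,
                                           bins = 32, theta_range_deg = 30) {
  nw <- dim(series$images)[3]
  centers <- series$window_center_timepoint
  if (is.null(n_timepoints)) n_timepoints <- max(centers)
  if (nw < 2) {
    z <- rep(0, n_timepoints)
    return(rigid_motion(z, z, z))
  }
  refs <- seq(1, nw, by = reference_stride)
  mags <- abs(series$images)
  est <- array(0, dim = c(nw, 3, length(refs)))
  score <- matrix(1, nw, length(refs))
  for (ri in seq_along(refs)) {
    fixed <- mags[, , refs[ri]]
    for (w in seq_len(nw)) {
      if (w == refs[ri]) {
        est[w, , ri] <- 0
        score[w, ri] <- 2
        next
      }
      tr <- register_rigid(mags[, , w], fixed, bins = bins,
                           theta_range_deg = theta_range_deg)
      # registration maps the moved image back onto the reference; the
      # object pose relative to the reference is the inverse transform
      est[w, , ri] <- pose_invert(tr$tx_mm, tr$ty_mm, tr$theta_deg)
      score[w, ri] <- tr$nmi
    }
  }
  # Bring every reference's relative poses into the first reference's
  # frame. The frame offset between reference r and reference 1 is itself a
  # rigid pose; it is estimated robustly as the parameter-wise median over
  # windows of inv(est_r(w)) o est_1(w), so single failed registrations
  # cannot displace a whole reference trajectory. With 10-25 degree
  # rotations this composition is essential: naive per-parameter
  # subtraction would alias translation between the axes. After alignment
  # the per-reference trajectories estimate the same pose sequence and are
  # averaged.
  for (ri in seq_along(refs)[-1]) {
    gw <- t(vapply(seq_len(nw), function(w)
      pose_compose(pose_invert(est[w, 1, ri], est[w, 2, ri], est[w, 3, ri]),
                   est[w, , 1]), numeric(3)))
    g <- apply(gw, 2, stats::median)
    for (w in seq_len(nw))
      est[w, , ri] <- pose_compose(est[w, , ri], g)
  }
  # Per-window robust combination. Registrations between windows whose
  # relative rotation approaches twice the motion amplitude can fail
  # outright (the similarity landscape loses the true optimum); a failed
  # reference must not drag the average. Where the aligned references
  # disagree by more than 2 px / 2 degrees, the window keeps the estimates
  # within tolerance of the best-scoring (highest NMI) reference.
  avg <- matrix(0, nw, 3)
  tol <- c(2 * pixel_mm, 2 * pixel_mm, 2)
  for (w in seq_len(nw)) {
    e <- matrix(est[w, , ], nrow = 3)
    spread <- apply(e, 1, function(v) diff(range(v)))
    if (all(spread <= tol)) {
      avg[w, ] <- rowMeans(e)
    } else {
      bestr <- which.max(score[w, ])
      keep <- which(colSums(abs(e - e[, bestr]) > tol) == 0)
      avg[w, ] <- rowMeans(e[, keep, drop = FALSE])
    }
  }
  m <- interpolate_motion(rigid_motion(avg[, 1] * pixel_mm,
                                       avg[, 2] * pixel_mm, avg[, 3]),
                          centers, n_timepoints)
  # Centre each parameter (common frame of reference for reporting). The
  # subtracted means are kept as the gauge offset: a pose sequence minus a
  # parameter constant is no longer a self-consistent sequence of rigid
  # poses, so the k-space correction restores the offset internally.
  gauge <- c(tx_mm = mean(m$tx_mm), ty_mm = mean(m$ty_mm),
             theta_deg = mean(m$theta_deg))
  m <- rigid_motion(m$tx_mm - gauge[1], m$ty_mm - gauge[2],
                    m$theta_deg - gauge[3])
  attr(m, "gauge_offset") <- gauge
  attr(m, "window_estimates") <- avg
  attr(m, "window_centers") <- centers
  m
}
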