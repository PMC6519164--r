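#' Iterative SENSE reconstruction of one k-space subset
#'
#' Conjugate-gradient solution of the density-weighted normal equations
#' \deqn{C^H S^H W S C x = C^H S^H W k}
#' with W the density-compensation weights, zero initialization and no
#' explicit regularization; the fixed, small iteration budget (15 by
#' default) regularizes the solution naturally. Stops early only when the
#' relative residual falls below \code{tol}.
#'
#' @param kdata complex M x Nc matrix of samples (or Ns x Nc x Nw array
#'   which is flattened).
#' @param coords M x 2 coordinate matrix, cycles/pixel.
#' @param dcf density weights, length M.
#' @param coils a [simulate_coil_maps()] object (or N x N x Nc array).
#' @param max_iter CG iteration budget.
#' @param tol relative residual tolerance.
#' @return Complex N x N image with attribute \code{"resnorm"} (residual
#'   norm per iteration, non-increasing).
#' @export
cg_sense <- function(kdata, coords, dcf, coils, max_iter = 15, tol = 1e-6) {
  cmaps <- if (inherits(coils, "coil_maps")) coils$maps else coils
  nc <- dim(cmaps)[3]
  kdata <- base::matrix(as.complex(kdata), ncol = nc)
  if (nrow(kdata) == 0) stopf("empty k-space subset")
  coords <- as_coord_matrix(coords)
  if (nrow(coords) != nrow(kdata)) stopf("`coords` and `kdata` disagree")
  dcf <- rep_len(as.numeric(dcf), nrow(coords))
  res <- cpp_cg_sense(kdata, coords[, 1], coords[, 2], dcf, cmaps,
                      as.integer(max_iter), tol, 2L, 7L)
  structure(res$image, resnorm = res$resnorm)
}

#' Sliding-window series of intermediate images
#'
#' Reconstructs auxiliary dynamic images from a moving block of consecutive
#' spokes with [cg_sense()], trading temporal resolution (window of 50 TRs
#' is about 200 ms at TR = 4.3 ms) for reduced aliasing. Density weights
#' are recomputed per window from the window's own spoke angles.
#'
#' @param kdata a [kspace_data()] object.
#' @param window window width in time points.
#' @param stride window step; 1 reconstructs every position, larger values
#'   trade correction fidelity for speed (skipped positions are
#'   interpolated at the motion-estimation stage).
#' @param max_iter,tol CG settings, see [cg_sense()].
#' @return An object of class \code{sliding_window_series}: \code{images}
#'   (N x N x Nw complex), \code{window_center_timepoint}, \code{window},
#'   \code{stride}.
#' @export
sliding_window_series <- function(kdata, window = 50, stride = 1,
                                  max_iter = 15, tol = 1e-6) {
  traj <- kdata$traj
  nt <- traj$n_timepoints
  if (window > nt) stopf("`window` exceeds the number of time points")
  starts <- seq(1, nt - window + 1, by = stride)
  n <- kdata$coils$matrix
  images <- array(0i, dim = c(n, n, length(starts)))
  centers <- integer(length(starts))
  for (w in seq_along(starts)) {
    tp <- starts[w]:(starts[w] + window - 1)
    dcf <- voronoi_dcf(traj, tp)
    kx <- as.vector(traj$coords[, 1, tp])
    ky <- as.vector(traj$coords[, 2, tp])
    kd <- base::matrix(aperm(kdata$samples[, , tp, drop = FALSE], c(1, 3, 2)),
                       ncol = dim(kdata$samples)[2])
    images[, , w] <- cg_sense(kd, cbind(kx, ky), as.vector(dcf), kdata$coils,
                              max_iter = max_iter, tol = tol)
    centers[w] <- floor(starts[w] + window / 2)
  }
  structure(list(images = images, window_center_timepoint = centers,
                 window = as.integer(window), stride = as.integer(stride)),
            class = "sliding_window_series")
}

#' @export
print.sliding_window_series <- function(x, ...) {
  cat(sprintf("<sliding_window_series> %d windows (width %d, stride %d)\n",
              dim(x$images)[3], x$window, x$stride))
  invisible(x)
}

#' Low-rank (subspace) inversion reconstruction
#'
#' Solves \deqn{\hat I = argmin_I || S U_R F C I - K ||^2_W} over the R
#' singular (coefficient) images directly: the forward operator combines
#' the coefficient images with row n of the temporal basis U_R,
#' coil-weights, and samples spoke n; conjugate gradient with zero
#' initialization and a fixed iteration budget. The reconstructed
#' time-point series is \code{U_R I}.
#'
#' @param kdata a [kspace_data()] object (typically motion-corrected).
#' @param basis either a \code{compressed_dictionary} or an Nt x R complex
#'   matrix with orthonormal columns.
#' @param dcf Ns x Nt density weights; default recomputes Voronoi weights
#'   from the trajectory (do this after motion correction).
#' @param max_iter,tol CG settings.
#' @return An object of class \code{singular_images}: \code{coeffs}
#'   (N x N x R complex), \code{basis}, \code{resnorm}.
#' @export
low_rank_inversion <- function(kdata, basis, dcf = NULL, max_iter = 15,
                               tol = 1e-6) {
  U <- if (inherits(basis, "compressed_dictionary")) basis$basis else basis
  traj <- kdata$traj
  nt <- traj$n_timepoints
  if (nrow(U) != nt) stopf("basis rows (%d) must match Nt (%d)", nrow(U), nt)
  if (is.null(dcf)) dcf <- voronoi_dcf(traj)
  dcf <- base::matrix(dcf, traj$n_samples, nt)
  res <- cpp_low_rank_inversion(
    kdata$samples,
    base::matrix(traj$coords[, 1, ], traj$n_samples, nt),
    base::matrix(traj$coords[, 2, ], traj$n_samples, nt),
    dcf, kdata$coils$maps, U, as.integer(max_iter), tol, 2L, 7L)
  structure(list(coeffs = res$coeffs, basis = U, resnorm = res$resnorm),
            class = "singular_images")
}

#' @export
print.singular_images <- function(x, ...) {
  d <- dim(x$coeffs)
  cat(sprintf("<singular_images> %d coefficient images of %d x %d\n",
              d[3], d[1], d[2]))
  invisible(x)
}

#' Project singular images to the time-point series
#'
#' @param singular a [low_rank_inversion()] result.
#' @param timepoints which time points to synthesize (default all).
#' @return Complex N x N x length(timepoints) array.
#' @export
project_timeseries <- function(singular, timepoints = NULL) {
  U <- singular$basis
  if (is.null(timepoints)) timepoints <- seq_len(nrow(U))
  d <- dim(singular$coeffs)
  cmat <- base::matrix(singular$coeffs, d[1] * d[2], d[3])
  out <- cmat %*% t(U[timepoints, , drop = FALSE])
  array(out, dim = c(d[1], d[2], length(timepoints)))
}
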