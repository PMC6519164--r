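#' Parametric maps container
#'
#' @param t1_ms,t2_ms,m0_magnitude,match_correlation N x N matrices.
#' @return An object of class \code{parametric_maps}.
#' @keywords internal
parametric_maps <- function(t1_ms, t2_ms, m0_magnitude, match_correlation) {
  structure(list(t1_ms = t1_ms, t2_ms = t2_ms, m0_magnitude = m0_magnitude,
                 match_correlation = match_correlation),
            class = "parametric_maps")
}

#' @export
print.parametric_maps <- function(x, ...) {
  cat(sprintf("<parametric_maps> %d x %d; T1 in [%g, %g] ms, T2 in [%g, %g] ms\n",
              nrow(x$t1_ms), ncol(x$t1_ms), min(x$t1_ms), max(x$t1_ms),
              min(x$t2_ms), max(x$t2_ms)))
  invisible(x)
}

# core inner-product matcher: signals (D x Npx), atoms (D x Na, same domain)
match_core <- function(signals, atoms, entries, out_dim, chunk = 4096) {
  anorm <- sqrt(colSums(Mod(atoms)^2))
  ahat <- sweep(atoms, 2, anorm, "/")
  npx <- ncol(signals)
  best <- integer(npx); corr <- numeric(npx); m0 <- numeric(npx)
  for (lo in seq(1, npx, by = chunk)) {
    hi <- min(lo + chunk - 1, npx)
    sc <- Mod(Conj(t(ahat)) %*% signals[, lo:hi, drop = FALSE])  # Na x chunk
    idx <- max.col(t(sc), ties.method = "first")
    best[lo:hi] <- idx
    top <- sc[cbind(idx, seq_len(hi - lo + 1))]
    snorm <- sqrt(colSums(Mod(signals[, lo:hi, drop = FALSE])^2))
    corr[lo:hi] <- ifelse(snorm > 0, top / snorm, 0)
    m0[lo:hi] <- top / anorm[idx]
  }
  parametric_maps(
    t1_ms = matrix(entries$t1_ms[best], out_dim[1], out_dim[2]),
    t2_ms = matrix(entries$t2_ms[best], out_dim[1], out_dim[2]),
    m0_magnitude = matrix(m0, out_dim[1], out_dim[2]),
    match_correlation = matrix(corr, out_dim[1], out_dim[2]))
}

#' Dictionary matching of singular images (compressed domain)
#'
#' Per-pixel inner-product template matching in the rank-R subspace: the
#' best atom maximizes \eqn{|\langle \hat c_a, s \rangle|} over the
#' unit-normalized compressed atoms, which is equivalent to time-domain
#' matching because the basis columns are orthonormal. T1/T2 are read off
#' the winning atom; M0 is \eqn{|\langle c_{a^*}, s \rangle| /
#' \|c_{a^*}\|^2}. Ties break to the lowest atom index.
#'
#' @param singular a [low_rank_inversion()] result.
#' @param cdict the [compress_dictionary()] the reconstruction basis came
#'   from (an error is raised on a basis mismatch).
#' @return A \code{parametric_maps} object.
#' @export
match_singular <- function(singular, cdict) {
  if (!inherits(cdict, "compressed_dictionary"))
    stopf("`cdict` must be a compressed_dictionary")
  if (!isTRUE(all.equal(dim(singular$basis), dim(cdict$basis))) ||
      max(Mod(singular$basis - cdict$basis)) > 1e-8)
    stopf("the singular images were reconstructed in a different basis")
  d <- dim(singular$coeffs)
  signals <- t(base::matrix(singular$coeffs, d[1] * d[2], d[3]))  # R x Npx
  match_core(signals, cdict$compressed_atoms, cdict$parent$entries, d)
}

#' Dictionary matching of a time-point image series
#'
#' Inner-product matching in the uncompressed Nt-dimensional domain; used
#' by the image-based correction baseline and for validation. When the
#' series covers only a subset of time points (e.g. window centres), pass
#' their indices and the atoms are subset to the same rows.
#'
#' @param images complex N x N x Nt (or x length(timepoints)) array.
#' @param dict an [build_dictionary()] object.
#' @param timepoints optional time-point indices matching the third array
#'   dimension.
#' @return A \code{parametric_maps} object.
#' @export
match_timeseries <- function(images, dict, timepoints = NULL) {
  if (!inherits(dict, "mrf_dictionary")) stopf("`dict` must be an mrf_dictionary")
  d <- dim(images)
  atoms <- dict$atoms
  if (!is.null(timepoints)) atoms <- atoms[timepoints, , drop = FALSE]
  if (d[3] != nrow(atoms)) stopf("series length disagrees with the dictionary")
  signals <- t(base::matrix(images, d[1] * d[2], d[3]))
  match_core(signals, atoms, dict$entries, d)
}

#' Image-based motion correction (IBMC) baseline
#'
#' Registers every sliding-window image to the first window (single
#' reference), resamples each image to the reference pose, assigns each
#' aligned image to its window-centre time point, and performs dictionary
#' matching on the aligned series. No k-space correction is involved, so
#' residual within-window motion and interpolation blur remain — this is
#' the baseline the k-space corrected reconstruction is compared against.
#'
#' @param series a [sliding_window_series()] object.
#' @param dict an [build_dictionary()] object.
#' @param bins,theta_range_deg registration settings, see
#'   [register_rigid()].
#' @return A \code{parametric_maps} object; the per-window transforms are
#'   attached as attribute \code{"transforms"}.
#' @export
ibmc_pipeline <- function(series, dict, bins = 32, theta_range_deg = 30) {
  nw <- dim(series$images)[3]
  aligned <- series$images
  trs <- base::matrix(0, nw, 3)
  fixed <- abs(series$images[, , 1])
  for (w in seq_len(nw)) {
    if (w > 1) {
      tr <- register_rigid(abs(series$images[, , w]), fixed, bins = bins,
                           theta_range_deg = theta_range_deg)
      trs[w, ] <- c(tr$tx_mm, tr$ty_mm, tr$theta_deg)
      aligned[, , w] <- cpp_apply_rigid(series$images[, , w], tr$tx_mm,
                                        tr$ty_mm, tr$theta_deg * pi / 180)
    }
  }
  pm <- match_timeseries(aligned, dict,
                         timepoints = series$window_center_timepoint)
  attr(pm, "transforms") <- trs
  pm
}
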