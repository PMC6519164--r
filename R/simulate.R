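#' Multi-coil radial MRF k-space container
#'
#' @param samples complex Ns x Nc x Nt array of k-space samples.
#' @param traj the matching [golden_radial()] trajectory.
#' @param coils the matching [simulate_coil_maps()] (or measured) maps.
#' @param seq the [sequence_params()] the data were acquired with.
#' @return An object of class \code{kspace_data}.
#' @export
kspace_data <- function(samples, traj, coils, seq = NULL) {
  d <- dim(samples)
  if (length(d) != 3) stopf("`samples` must be Ns x Nc x Nt")
  if (d[1] != traj$n_samples || d[3] != traj$n_timepoints)
    stopf("`samples` dimensions disagree with the trajectory")
  if (d[2] != dim(coils$maps)[3]) stopf("coil count mismatch")
  structure(list(samples = samples, traj = traj, coils = coils, seq = seq),
            class = "kspace_data")
}

#' @export
print.kspace_data <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<kspace_data> %d samples x %d coils x %d time points\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Simulate multi-coil radial MRF k-space under rigid motion
#'
#' Forward simulation of the acquisition: at each time point n the contrast
#' image \code{m0(r) * f(T1(r), T2(r))[n]} is formed by exact per-pixel
#' lookup of the fingerprints of the unique (T1, T2) classes in the
#' phantom, moved to the motion state of time point n (see
#' \code{motion_model}), coil-weighted, and sampled on spoke n with the
#' gridding NUFFT. Complex
#' Gaussian noise of standard deviation \code{noise_sd} (per real/imaginary
#' channel, relative to the unit-M0 signal scale) is added with a fixed
#' seed, so the data are reproducible.
#'
#' The signal model is the same EPG simulation used for dictionary
#' building; passing a \code{signal_model} built with a finer slice-profile
#' discretization gives an inverse-crime-free test set.
#'
#' @param maps a [tissue_maps()] phantom.
#' @param seq a [sequence_params()] object.
#' @param signal_model an \code{mrf_dictionary} whose entries cover every
#'   (T1, T2) value present in \code{maps} (exact lookup; an error is
#'   raised otherwise), or \code{NULL} to simulate the needed fingerprints
#'   on the fly with \code{profile}.
#' @param traj a [golden_radial()] trajectory with \code{Nt} spokes.
#' @param coils a [simulate_coil_maps()] object.
#' @param motion a [rigid_motion()] trajectory of length Nt (default none).
#' @param noise_sd complex-noise standard deviation (0 = noiseless).
#' @param seed RNG seed for the noise.
#' @param profile slice profile for on-the-fly fingerprints.
#' @param motion_model how motion enters the forward model.
#'   \code{"kspace"} (default) modifies the motion-free k-space exactly:
#'   spoke n samples the static coil-weighted spectrum at coordinates
#'   rotated by the motion state, with the translation as a phase ramp —
#'   the classical way motion experiments are synthesized from a
#'   motion-free acquisition, and exact to machine precision.
#'   \code{"image"} transforms the contrast image in the image domain
#'   (bilinear interpolation) before coil weighting and sampling, which
#'   avoids sharing the correction's k-space motion representation and so
#'   provides an inverse-crime-free check at the cost of interpolation
#'   error.
#' @return A [kspace_data()] object; the ground-truth motion is attached as
#'   attribute \code{"motion_truth"}.
#' @export
simulate_mrf_kspace <- function(maps, seq, signal_model = NULL, traj, coils,
                                motion = NULL, noise_sd = 0, seed = 1,
                                profile = slice_profile(),
                                motion_model = c("kspace", "image")) {
  motion_model <- match.arg(motion_model)
  if (!inherits(maps, "tissue_maps")) stopf("`maps` must be a tissue_maps object")
  nt <- traj$n_timepoints
  if (seq$n_timepoints != nt) stopf("sequence and trajectory disagree on Nt")
  if (maps$matrix != coils$matrix) stopf("phantom and coil geometry disagree")
  if (is.null(motion)) motion <- rigid_motion(rep(0, nt), rep(0, nt), rep(0, nt))
  if (motion$n_timepoints != nt) stopf("motion trajectory must have length Nt")

  # unique tissue classes and their fingerprints
  key <- paste(maps$t1_ms, maps$t2_ms, sep = "/")
  inside <- which(maps$mask)
  ukey <- unique(key[inside])
  ut <- do.call(rbind, strsplit(ukey, "/"))
  ut1 <- as.numeric(ut[, 1]); ut2 <- as.numeric(ut[, 2])
  if (is.null(signal_model)) {
    fp <- cpp_epg_fisp(ut1, ut2, seq$flip_angles, seq$tr_ms, seq$te_ms,
                       pmax(profile$scale, 1e-12), seq$invert,
                       as.integer(min(nt, 100L)))
  } else {
    idx <- base::match(ukey, paste(signal_model$entries$t1_ms,
                                   signal_model$entries$t2_ms, sep = "/"))
    if (anyNA(idx))
      stopf("signal model lacks fingerprints for phantom values: %s",
            paste(head(ukey[is.na(idx)], 5), collapse = ", "))
    fp <- signal_model$atoms[, idx, drop = FALSE]
  }

  n <- maps$matrix
  comp <- array(0i, dim = c(n, n, length(ukey)))
  for (t in seq_along(ukey)) {
    cm <- base::matrix(0i, n, n)
    sel <- inside[key[inside] == ukey[t]]
    cm[sel] <- maps$m0[sel]
    comp[, , t] <- cm
  }

  px <- maps$pixel_mm
  simfun <- if (motion_model == "kspace") cpp_simulate_kspace_rotated
            else cpp_simulate_kspace
  samples <- simfun(comp, fp, motion$tx_mm / px, motion$ty_mm / px,
                    motion$theta_deg * pi / 180,
                    base::matrix(traj$coords[, 1, ], traj$n_samples, nt),
                    base::matrix(traj$coords[, 2, ], traj$n_samples, nt),
                    coils$maps, 2L, 7L)
  if (noise_sd > 0) {
    noise <- with_seed(seed, {
      array(complex(real = rnorm(length(samples), sd = noise_sd),
                    imaginary = rnorm(length(samples), sd = noise_sd)),
            dim = dim(samples))
    })
    samples <- samples + noise
  }
  out <- kspace_data(samples, traj, coils, seq)
  attr(out, "motion_truth") <- motion
  out
}
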