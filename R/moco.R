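#' Correct acquired k-space for estimated rigid motion
#'
#' Inverts the estimated object motion directly on the raw data: for time
#' point n with rotation \eqn{\theta_n} and translation \eqn{t_n}, the
#' spoke coordinates are rotated by \eqn{-\theta_n} (the inverse-transpose
#' of the image rotation, about DC) and the samples are multiplied by the
#' unit-magnitude phase ramp \eqn{e^{+2\pi i k \cdot t_n}} evaluated at the
#' original coordinates. Sample magnitudes are preserved exactly (the
#' rigid-motion determinant is 1). Density weights are not stored here:
#' recompute them from the corrected trajectory per reconstruction (spoke
#' rotations change the angular distribution).
#'
#' The sign convention is fixed by the round-trip requirement that
#' correcting data simulated under a motion trajectory with that same
#' trajectory reproduces the motion-free acquisition; both signs are
#' available for diagnostic use.
#'
#' @param data a [kspace_data()] object.
#' @param motion a [rigid_motion()] of length Nt (e.g. from
#'   [estimate_motion_multireference()]).
#' @param pixel_mm pixel size in mm (converts the motion translations to
#'   pixel units matching the normalized trajectory).
#' @param phase_sign,rotation_sign sign overrides (+1/-1) for the
#'   translation phase ramp and the trajectory rotation.
#' @return A [kspace_data()] object with corrected samples and trajectory.
#' @export
correct_kspace <- function(data, motion, pixel_mm, phase_sign = +1,
                           rotation_sign = -1) {
  traj <- data$traj
  nt <- traj$n_timepoints
  if (motion$n_timepoints != nt) stopf("motion length must equal Nt")
  # restore the gauge offset subtracted for reporting (see
  # estimate_motion_multireference): the correction must apply a
  # self-consistent sequence of poses; the constant offset only moves the
  # frame of the corrected reconstruction
  g <- attr(motion, "gauge_offset")
  if (is.null(g)) g <- c(0, 0, 0)
  txp <- (motion$tx_mm + g[1]) / pixel_mm
  typ <- (motion$ty_mm + g[2]) / pixel_mm
  thr <- rotation_sign * (motion$theta_deg + g[3]) * pi / 180
  samples <- data$samples
  coords <- traj$coords
  angles <- traj$angles
  for (n in seq_len(nt)) {
    if (txp[n] != 0 || typ[n] != 0) {
      ph <- exp(phase_sign * 2i * pi *
                  (coords[, 1, n] * txp[n] + coords[, 2, n] * typ[n]))
      for (c in seq_len(dim(samples)[2])) samples[, c, n] <- samples[, c, n] * ph
    }
    if (thr[n] != 0) {
      ct <- cos(thr[n]); st <- sin(thr[n])
      kx <- coords[, 1, n]; ky <- coords[, 2, n]
      coords[, 1, n] <- ct * kx - st * ky
      coords[, 2, n] <- st * kx + ct * ky
      angles[n] <- (angles[n] + thr[n]) %% pi
    }
  }
  # rotation can land the spoke-end sample exactly on +0.5; wrap those
  # samples onto the periodic interval, which leaves the Fourier sums
  # unchanged
  coords[coords >= 0.5] <- coords[coords >= 0.5] - 1
  coords[coords < -0.5] <- coords[coords < -0.5] + 1
  traj$coords <- coords
  traj$angles <- angles
  out <- kspace_data(samples, traj, data$coils, data$seq)
  attr(out, "motion_applied") <- motion
  out
}
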