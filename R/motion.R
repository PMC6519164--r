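#' Rigid motion trajectory
#'
#' One rigid-body state per time point (= per TR, since one spoke is
#' acquired per TR): translations in mm and in-plane rotation in degrees.
#'
#' @param tx_mm,ty_mm,theta_deg numeric vectors of equal length Nt.
#' @return An object of class \code{rigid_motion}.
#' @export
rigid_motion <- function(tx_mm, ty_mm, theta_deg) {
  nt <- length(tx_mm)
  if (length(ty_mm) != nt || length(theta_deg) != nt)
    stopf("motion components must have equal length")
  if (any(!is.finite(c(tx_mm, ty_mm, theta_deg))))
    stopf("motion parameters must be finite")
  structure(list(tx_mm = as.numeric(tx_mm), ty_mm = as.numeric(ty_mm),
                 theta_deg = as.numeric(theta_deg), n_timepoints = nt),
            class = "rigid_motion")
}

#' @export
print.rigid_motion <- function(x, ...) {
  cat(sprintf("<rigid_motion> %d time points; |tx|<=%.3g mm, |ty|<=%.3g mm, |theta|<=%.3g deg\n",
              x$n_timepoints, max(abs(x$tx_mm)), max(abs(x$ty_mm)),
              max(abs(x$theta_deg))))
  invisible(x)
}

#' Abrupt (step) rigid motion
#'
#' Zero motion before \code{event_timepoint}; constant
#' \code{(tx, ty, theta)} from the event onward. Translation amplitudes are
#' given in pixels and converted to mm via \code{pixel_mm}, mirroring how
#' motion amplitudes are quoted for simulated acquisitions.
#'
#' @param n_timepoints trajectory length Nt.
#' @param event_timepoint time point at which the step occurs
#'   (\code{1 <= event < Nt}).
#' @param tx_px,ty_px translation amplitudes in pixels.
#' @param theta_deg rotation amplitude in degrees.
#' @param pixel_mm pixel size in mm.
#' @return A [rigid_motion()] object.
#' @export
motion_abrupt <- function(n_timepoints, event_timepoint, tx_px, ty_px,
                          theta_deg, pixel_mm) {
  check_number(event_timepoint, "event_timepoint", lower = 1,
               upper = n_timepoints - 1)
  on <- seq_len(n_timepoints) > event_timepoint
  rigid_motion(ifelse(on, tx_px * pixel_mm, 0),
               ifelse(on, ty_px * pixel_mm, 0),
               ifelse(on, theta_deg, 0))
}

#' Sinusoidally varying rigid motion
#'
#' Each parameter follows \code{amplitude * sin(2 pi n_cycles n / Nt)};
#' quoted amplitudes are peak values (peak-to-peak is twice the amplitude).
#'
#' @inheritParams motion_abrupt
#' @param n_cycles number of full motion cycles over the scan.
#' @return A [rigid_motion()] object.
#' @export
motion_sinusoidal <- function(n_timepoints, tx_px, ty_px, theta_deg,
                              n_cycles = 3, pixel_mm) {
  s <- sin(2 * pi * n_cycles * seq_len(n_timepoints) / n_timepoints)
  rigid_motion(tx_px * pixel_mm * s, ty_px * pixel_mm * s, theta_deg * s)
}

#' Apply a rigid transform to an image
#'
#' Rotates by \code{theta_deg} about the image centre (pixel
#' \code{(N/2, N/2)}, which coincides with the k-space DC convention) and
#' then translates; bilinear interpolation, zero fill outside the FOV.
#'
#' @param image numeric or complex matrix.
#' @param tx_mm,ty_mm translation along the first/second array dimension, mm.
#' @param theta_deg rotation angle, degrees.
#' @param pixel_mm pixel size in mm.
#' @return Transformed image, same storage mode as the input.
#' @export
apply_rigid <- function(image, tx_mm, ty_mm, theta_deg, pixel_mm = 1) {
  out <- cpp_apply_rigid(complex_array(image, dim(image)),
                         tx_mm / pixel_mm, ty_mm / pixel_mm,
                         theta_deg * pi / 180)
  if (is.complex(image)) out else Re(out)
}

# Pose algebra: a pose p = (tx, ty, theta) acts on images as
# out(x) = in(R_{-theta}(x - t)). Composition and inversion are exact.
pose_invert <- function(tx, ty, theta_deg) {
  th <- theta_deg * pi / 180
  c(tx = -(cos(th) * tx + sin(th) * ty),
    ty = -(-sin(th) * tx + cos(th) * ty),
    theta_deg = -theta_deg)
}

# pose of "apply b, then a": theta = theta_a + theta_b, t = t_a + R_{theta_a} t_b
pose_compose <- function(a, b) {
  th <- a[3] * pi / 180
  c(tx = a[1] + cos(th) * b[1] - sin(th) * b[2],
    ty = a[2] + sin(th) * b[1] + cos(th) * b[2],
    theta_deg = a[3] + b[3])
}

#' Interpolate motion defined at window centres to every time point
#'
#' Linear interpolation with constant extrapolation at the ends.
#'
#' @param motion a [rigid_motion()] sampled at \code{timepoints}.
#' @param timepoints time points the motion states correspond to.
#' @param n_timepoints target trajectory length.
#' @return A [rigid_motion()] of length \code{n_timepoints}.
#' @export
interpolate_motion <- function(motion, timepoints, n_timepoints) {
  tp <- seq_len(n_timepoints)
  if (length(timepoints) == 1) {
    return(rigid_motion(rep(motion$tx_mm, n_timepoints),
                        rep(motion$ty_mm, n_timepoints),
                        rep(motion$theta_deg, n_timepoints)))
  }
  rigid_motion(interp_constant_ends(timepoints, motion$tx_mm, tp),
               interp_constant_ends(timepoints, motion$ty_mm, tp),
               interp_constant_ends(timepoints, motion$theta_deg, tp))
}
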