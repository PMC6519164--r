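#' Sequence parameters for a FISP-type MRF acquisition
#'
#' Bundles the flip-angle train and timing of an inversion-prepared,
#' gradient-spoiled, fixed-TR fingerprinting sequence. Defaults follow the
#' protocol the package emulates: TE/TR = 1.23/4.3 ms, 1750 time points, one
#' golden-angle radial spoke per TR, inversion pulse before the first TR.
#'
#' @param flip_angles numeric vector of flip angles in degrees, one per time
#'   point, each in \code{[0, 180]}.
#' @param tr_ms repetition time in ms (fixed across the train).
#' @param te_ms echo time in ms; must satisfy \code{0 < te_ms < tr_ms}.
#' @param invert logical; apply an ideal 180 degree inversion pulse before
#'   the first TR.
#' @return An object of class \code{sequence_params} with fields
#'   \code{flip_angles}, \code{tr_ms}, \code{te_ms}, \code{invert},
#'   \code{n_timepoints}.
#' @seealso [mrf_flip_angle_schedule()] for the default flip-angle generator,
#'   [epg_fisp_signal()] for the signal model.
#' @export
sequence_params <- function(flip_angles, tr_ms = 4.3, te_ms = 1.23,
                            invert = TRUE) {
  if (length(flip_angles) < 1) stopf("`flip_angles` must have length >= 1")
  if (!is.numeric(flip_angles) || any(!is.finite(flip_angles)))
    stopf("`flip_angles` must be finite numeric")
  if (any(flip_angles < 0 | flip_angles > 180))
    stopf("flip angles must lie in [0, 180] degrees")
  check_number(tr_ms, "tr_ms", lower = 1e-6)
  check_number(te_ms, "te_ms", lower = 1e-9)
  if (te_ms >= tr_ms) stopf("`te_ms` must be smaller than `tr_ms`")
  structure(
    list(flip_angles = as.numeric(flip_angles), tr_ms = tr_ms, te_ms = te_ms,
         invert = isTRUE(invert), n_timepoints = length(flip_angles)),
    class = "sequence_params")
}

#' @export
print.sequence_params <- function(x, ...) {
  cat(sprintf(
    "<sequence_params> %d time points, TR %.3g ms, TE %.3g ms, FA %.3g-%.3g deg%s\n",
    x$n_timepoints, x$tr_ms, x$te_ms, min(x$flip_angles), max(x$flip_angles),
    if (x$invert) ", inversion-prepared" else ""))
  invisible(x)
}

#' Default MRF flip-angle schedule
#'
#' Generates a train of sinusoidal flip-angle half-lobes whose peak
#' amplitudes ramp up to \code{peak_deg}, with a small deterministic
#' pseudo-random jitter. This emulates the class of smoothly varying
#' 0-70 degree patterns used by FISP-type MRF protocols; the exact waveform
#' is freely overridable (any numeric vector, or [read_flip_angles_csv()]).
#'
#' @param n_timepoints number of TRs.
#' @param n_lobes number of half-lobes across the train.
#' @param peak_deg peak flip angle of the final lobe, degrees.
#' @param min_peak_frac peak of the first lobe as a fraction of
#'   \code{peak_deg}.
#' @param jitter_frac amplitude of the per-TR multiplicative jitter.
#' @return Numeric vector of flip angles in degrees, length
#'   \code{n_timepoints}, starting at 0.
#' @export
mrf_flip_angle_schedule <- function(n_timepoints = 1750, n_lobes = 10,
                                    peak_deg = 70, min_peak_frac = 0.25,
                                    jitter_frac = 0.03) {
  check_number(n_timepoints, "n_timepoints", lower = 1)
  lobe_len <- n_timepoints / n_lobes
  idx <- seq_len(n_timepoints) - 1
  lobe <- pmin(floor(idx / lobe_len), n_lobes - 1)
  phase <- (idx - lobe * lobe_len) / lobe_len
  ramp <- if (n_lobes > 1) min_peak_frac + (1 - min_peak_frac) * lobe / (n_lobes - 1)
          else 1
  fa <- peak_deg * ramp * sin(pi * phase)
  jit <- 1 + jitter_frac * (2 * lcg_runif(n_timepoints) - 1)
  pmax(0, pmin(180, fa * jit))
}

#' Read a flip-angle schedule from a two-column CSV
#'
#' The file must contain columns \code{index} and \code{degrees}; rows are
#' sorted by index before use.
#'
#' @param path CSV file path.
#' @return Numeric vector of flip angles in degrees.
#' @export
read_flip_angles_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("index", "degrees") %in% names(d)))
    stopf("flip-angle CSV must have columns `index` and `degrees`")
  as.numeric(d$degrees[order(d$index)])
}
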