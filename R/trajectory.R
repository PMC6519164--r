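#' The 2D golden angle in radians
#'
#' \code{pi * (sqrt(5) - 1) / 2}, i.e. 111.2461... degrees, the azimuthal
#' increment that keeps any contiguous set of radial spokes near-uniformly
#' distributed.
#' @export
golden_angle <- function() pi * (sqrt(5) - 1) / 2

#' Golden-angle radial trajectory
#'
#' One radial spoke per time point with spoke angle \code{n * golden_angle()
#' mod pi}. Each spoke carries \code{n_samples} samples at signed radii
#' \code{(-Ns/2, ..., Ns/2 - 1) / Ns} cycles/pixel, i.e. spanning the
#' Nyquist extent of the reconstruction matrix through DC.
#'
#' @param n_timepoints number of time points (= spokes).
#' @param n_samples samples per spoke.
#' @param matrix reconstruction matrix size (records the grid the
#'   normalized coordinates refer to).
#' @return An object of class \code{radial_trajectory}: \code{coords}
#'   (Ns x 2 x Nt array, cycles/pixel in \code{[-0.5, 0.5)}), \code{angles}
#'   (radians per time point), \code{radii} (signed, length Ns), \code{dr},
#'   \code{matrix}.
#' @export
golden_radial <- function(n_timepoints, n_samples = 160, matrix = 160) {
  check_number(n_timepoints, "n_timepoints", lower = 1)
  check_number(n_samples, "n_samples", lower = 1)
  angles <- ((seq_len(n_timepoints) - 1) * golden_angle()) %% pi
  radii <- (seq_len(n_samples) - 1 - n_samples / 2) / n_samples
  coords <- array(0, dim = c(n_samples, 2, n_timepoints))
  for (n in seq_len(n_timepoints)) {
    coords[, 1, n] <- radii * cos(angles[n])
    coords[, 2, n] <- radii * sin(angles[n])
  }
  structure(list(coords = coords, angles = angles, radii = radii,
                 dr = 1 / n_samples, matrix = as.integer(matrix),
                 n_samples = as.integer(n_samples),
                 n_timepoints = as.integer(n_timepoints)),
            class = "radial_trajectory")
}

#' @export
print.radial_trajectory <- function(x, ...) {
  cat(sprintf("<radial_trajectory> %d spokes x %d samples, matrix %d\n",
              x$n_timepoints, x$n_samples, x$matrix))
  invisible(x)
}

#' Voronoi density compensation for radial spokes
#'
#' Per-sample k-space density weights equal to the polar Voronoi cell area
#' of each sample. Because every spoke passes through DC with uniform radial
#' spacing, the Voronoi cells are polar wedges bounded radially by the
#' midpoints between consecutive samples and angularly by the bisectors to
#' the neighbouring spoke directions; their areas are computed in closed
#' form from the sorted spoke directions. Duplicate spokes share their cell
#' area equally, the shared DC samples split the central disk, outer cells
#' are clipped to the sampled disk, and weights are normalized so their sum
#' equals the disk area. A single distinct spoke direction has no Voronoi
#' neighbours; a ramp |k| fallback is returned with a warning.
#'
#' @param traj a [golden_radial()] trajectory (possibly motion-corrected).
#' @param timepoints indices of the spokes to include (default all); the
#'   weights of a subset differ from the full set's, so they are recomputed
#'   per reconstruction window.
#' @return Ns x length(timepoints) matrix of weights.
#' @export
voronoi_dcf <- function(traj, timepoints = NULL) {
  if (is.null(timepoints)) timepoints <- seq_len(traj$n_timepoints)
  angles <- traj$angles[timepoints] %% pi
  radii <- traj$radii
  dr <- traj$dr
  ns <- length(radii)
  nsp <- length(angles)

  key <- round(angles / 1e-9)
  mult <- table(key)[as.character(key)]
  mult <- as.numeric(mult)

  uang <- unique(angles[!duplicated(key)])
  if (length(uang) < 2) {
    warning("single distinct spoke direction; falling back to ramp |k| weights")
    w <- abs(radii)
    w[w == 0] <- dr / 4
    w <- w / mean(mult)
    out <- matrix(rep(w, nsp), ns, nsp)
    disk_r <- max(abs(radii)) + dr / 2
    return(out * (pi * disk_r^2 / sum(out)))
  }

  # full-circle directions: each spoke contributes theta and theta + pi
  ukey <- unique(key)
  dkey <- c(ukey, ukey + round(pi / 1e-9))
  dang <- c(uang, uang + pi)
  ord <- order(dang)
  dang <- dang[ord]; dkey <- dkey[ord]
  nd <- length(dang)
  nxt <- c(dang[-1], dang[1] + 2 * pi)
  prv <- c(dang[nd] - 2 * pi, dang[-nd])
  wedge <- setNames((nxt - prv) / 2, dkey)
  wpos <- wedge[as.character(key)]
  wneg <- wedge[as.character(key + round(pi / 1e-9))]

  disk_r <- max(abs(radii)) + dr / 2
  n0 <- sum(radii == 0) * nsp
  inner <- pmax(abs(radii) - dr / 2, 0)
  outer <- pmin(abs(radii) + dr / 2, disk_r)
  ring <- (outer^2 - inner^2) / 2
  out <- matrix(0, ns, nsp)
  for (j in seq_len(nsp)) {
    w <- ifelse(radii > 0, wpos[j], wneg[j]) * ring / mult[j]
    w[radii == 0] <- pi * (dr / 2)^2 / max(n0, 1)
    out[, j] <- w
  }
  out * (pi * disk_r^2 / sum(out))
}

#' Angular coverage report for a (corrected) radial trajectory
#'
#' Rotating spokes during motion correction disturbs the quasi-uniform
#' golden-angle distribution and opens angular gaps in k-space, which makes
#' the subsequent reconstruction more ill-conditioned. This QC helper
#' reports the sorted spoke-angle gaps modulo pi.
#'
#' @param traj a [golden_radial()] trajectory (typically after
#'   [correct_kspace()]).
#' @param bins number of histogram bins over \code{[0, pi)}.
#' @return A list with \code{max_gap_rad}, \code{gaps_rad} (per sorted
#'   angle), and \code{histogram} (counts of spoke angles per bin).
#' @export
residual_kspace_coverage <- function(traj, bins = 36) {
  a <- sort(traj$angles %% pi)
  gaps <- diff(c(a, a[1] + pi))
  h <- tabulate(pmin(floor(a / pi * bins) + 1, bins), nbins = bins)
  list(max_gap_rad = max(gaps), gaps_rad = gaps, histogram = h)
}
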