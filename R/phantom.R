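#' Tissue parameter maps
#'
#' Container for per-pixel T1/T2/M0 ground truth. Values are zero outside
#' the object mask and contribute no signal there.
#'
#' @param t1_ms,t2_ms numeric N x N matrices (ms), positive inside the mask.
#' @param m0 complex (or numeric) N x N proton-density amplitude.
#' @param mask logical N x N object mask.
#' @param fov_mm field of view in mm.
#' @return An object of class \code{tissue_maps}; also carries
#'   \code{matrix} and \code{pixel_mm = fov_mm / matrix}.
#' @export
tissue_maps <- function(t1_ms, t2_ms, m0, mask, fov_mm) {
  n <- nrow(t1_ms)
  stopifnot(all(dim(t1_ms) == c(n, n)), all(dim(t2_ms) == c(n, n)),
            all(dim(m0) == c(n, n)), all(dim(mask) == c(n, n)))
  mask <- mask & is.finite(t1_ms) & is.finite(t2_ms)
  if (any(t1_ms[mask] <= 0) || any(t2_ms[mask] <= 0))
    stopf("T1 and T2 must be positive inside the mask")
  m0c <- complex_array(m0, dim(m0))
  m0c[!mask] <- 0i
  t1_ms[!mask] <- 0
  t2_ms[!mask] <- 0
  structure(list(t1_ms = t1_ms, t2_ms = t2_ms, m0 = m0c, mask = mask,
                 fov_mm = fov_mm, matrix = n, pixel_mm = fov_mm / n),
            class = "tissue_maps")
}

ellipse_mask <- function(n, cx, cy, rx, ry, theta = 0, wave = NULL) {
  x <- matrix(rep(seq_len(n) - 1 - n / 2, n), n, n) - cx
  y <- t(matrix(rep(seq_len(n) - 1 - n / 2, n), n, n)) - cy
  ct <- cos(theta); st <- sin(theta)
  u <- ct * x + st * y
  v <- -st * x + ct * y
  r2 <- (u / rx)^2 + (v / ry)^2
  if (is.null(wave)) return(r2 <= 1)
  # angularly modulated ("folded") boundary: r(phi) scaled by 1 + wave(phi)
  phi <- atan2(v / ry, u / rx)
  scl <- 1
  for (k in seq_along(wave$amp))
    scl <- scl + wave$amp[k] * sin(wave$freq[k] * phi + wave$phase[k])
  r2 <= scl^2
}

#' Brain-like digital phantom
#'
#' Ellipse-based stand-in for an anatomical brain slice with realistic
#' relaxation values: white matter T1/T2 = 738/48 ms, gray matter
#' T1/T2 = 1127/69 ms, CSF T1/T2 = 4000/2000 ms (configurable), plus small
#' gray-matter inclusions for resolution assessment. Deterministic given
#' the geometry.
#'
#' @param matrix image matrix size N (>= 32).
#' @param fov_mm field of view in mm.
#' @param wm,gm,csf length-2 vectors \code{c(T1_ms, T2_ms)} per tissue.
#' @return A [tissue_maps()] object.
#' @export
brain_phantom <- function(matrix = 160, fov_mm = 320,
                          wm = c(738, 48), gm = c(1127, 69),
                          csf = c(4000, 2000)) {
  check_number(matrix, "matrix", lower = 32)
  n <- as.integer(matrix)
  r <- n / 2
  t1 <- base::matrix(0, n, n)
  t2 <- base::matrix(0, n, n)
  m0 <- base::matrix(0, n, n)
  paint <- function(msk, vals, dens) {
    t1[msk] <<- vals[1]; t2[msk] <<- vals[2]; m0[msk] <<- dens
  }
  head_m <- ellipse_mask(n, 0, 0, 0.78 * r, 0.92 * r)
  paint(head_m, gm, 0.85)                                    # cortical sheet
  # white matter with a folded (gyri-like) boundary; the angular structure
  # breaks the rotational quasi-symmetry so that rigid rotation is
  # identifiable by registration, as it is on real anatomy
  wm_wave <- list(amp = c(0.10, 0.06, 0.04), freq = c(7, 4, 3),
                  phase = c(0.8, 2.1, 4.0))
  paint(ellipse_mask(n, 0, 0, 0.62 * r, 0.76 * r, wave = wm_wave), wm, 0.80)
  # lateral ventricles (CSF), slightly asymmetric
  paint(ellipse_mask(n, -0.07 * r, -0.18 * r, 0.11 * r, 0.30 * r, 0.25), csf, 1)
  paint(ellipse_mask(n, -0.05 * r, 0.17 * r, 0.09 * r, 0.26 * r, -0.25), csf, 1)
  # deep gray nuclei
  paint(ellipse_mask(n, 0.18 * r, -0.14 * r, 0.10 * r, 0.07 * r, 0.4), gm, 0.85)
  paint(ellipse_mask(n, 0.20 * r, 0.13 * r, 0.08 * r, 0.07 * r, -0.2), gm, 0.85)
  # asymmetric cortical CSF sulci
  paint(ellipse_mask(n, -0.52 * r, 0.42 * r, 0.05 * r, 0.14 * r, 0.9), csf, 1)
  paint(ellipse_mask(n, 0.48 * r, -0.47 * r, 0.04 * r, 0.10 * r, -0.7), csf, 1)
  # small inclusions for resolution assessment
  for (k in 1:3) {
    rad <- 0.035 * r * k / 2
    paint(ellipse_mask(n, -0.40 * r, (k - 2) * 0.22 * r, rad, rad), gm, 0.9)
  }
  tissue_maps(t1, t2, m0, m0 > 0, fov_mm)
}

#' Vial phantom with prescribed T1/T2 values
#'
#' Circular vials on a regular grid, one per (T1, T2) pair; a stand-in for
#' a standardized relaxometry phantom. Choosing values on dictionary grid
#' nodes makes noiseless matching exact at the vial interiors.
#'
#' @param matrix image matrix size N.
#' @param fov_mm field of view in mm.
#' @param t1_list,t2_list equal-length vectors of per-vial values (ms).
#' @return A [tissue_maps()] object.
#' @export
vial_phantom <- function(matrix, fov_mm, t1_list, t2_list) {
  if (length(t1_list) == 0 || length(t1_list) != length(t2_list))
    stopf("`t1_list` and `t2_list` must be non-empty and of equal length")
  n <- as.integer(matrix)
  nv <- length(t1_list)
  g <- ceiling(sqrt(nv))
  t1 <- base::matrix(0, n, n)
  t2 <- base::matrix(0, n, n)
  m0 <- base::matrix(0, n, n)
  pitch <- 1.4 * n / (2 * g + 0.5)
  rad <- 0.32 * pitch
  for (v in seq_len(nv)) {
    gi <- (v - 1) %% g
    gj <- (v - 1) %/% g
    cx <- (gi - (g - 1) / 2) * pitch
    cy <- (gj - (g - 1) / 2) * pitch
    msk <- ellipse_mask(n, cx, cy, rad, rad)
    t1[msk] <- t1_list[v]
    t2[msk] <- t2_list[v]
    m0[msk] <- 1
  }
  tissue_maps(t1, t2, m0, m0 > 0, fov_mm)
}
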