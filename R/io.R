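# Container and map I/O -----------------------------------------------------

#' Write a raw MRF container
#'
#' Serializes k-space samples, trajectory, density weights, coil maps,
#' sequence and (when present) the ground-truth or estimated motion into a
#' single-file container (RDS) with a fixed layout of named slots
#' (\code{kdata}, \code{traj}, \code{dcf}, \code{coilmaps}, \code{seq},
#' \code{motion_truth}, \code{motion_estimate}).
#'
#' @param kdata a [kspace_data()] object.
#' @param path output file path.
#' @param dcf optional density weights to store.
#' @param motion_estimate optional estimated [rigid_motion()].
#' @export
write_mrf_container <- function(kdata, path, dcf = NULL,
                                motion_estimate = NULL) {
  saveRDS(list(format = "mrfmoco-raw-v1",
               kdata = kdata$samples, traj = kdata$traj, dcf = dcf,
               coilmaps = kdata$coils, seq = kdata$seq,
               motion_truth = attr(kdata, "motion_truth"),
               motion_estimate = motion_estimate),
          path)
  invisible(path)
}

#' Read a raw MRF container written by [write_mrf_container()]
#'
#' @param path container path.
#' @return A [kspace_data()] object; extra slots are attached as
#'   attributes.
#' @export
read_mrf_container <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "mrfmoco-raw-v1")) stopf("not an mrfmoco raw container")
  out <- kspace_data(x$kdata, x$traj, x$coilmaps, x$seq)
  attr(out, "motion_truth") <- x$motion_truth
  attr(out, "motion_estimate") <- x$motion_estimate
  attr(out, "dcf") <- x$dcf
  out
}

#' Write parametric maps as NIfTI files
#'
#' One file per parameter (\code{_t1.nii.gz}, \code{_t2.nii.gz},
#' \code{_m0.nii.gz}, \code{_corr.nii.gz}) with the pixel size recorded in
#' the header.
#'
#' @param pm a \code{parametric_maps} object.
#' @param prefix output path prefix.
#' @param pixel_mm pixel size in mm.
#' @return Invisibly, the written paths.
#' @export
write_maps_nifti <- function(pm, prefix, pixel_mm = 1) {
  planes <- list(t1 = pm$t1_ms, t2 = pm$t2_ms, m0 = pm$m0_magnitude,
                 corr = pm$match_correlation)
  paths <- character(0)
  for (nm in names(planes)) {
    p <- paste0(prefix, "_", nm, ".nii.gz")
    img <- RNifti::asNifti(planes[[nm]], pixdim = c(pixel_mm, pixel_mm))
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write an estimated motion trajectory as CSV
#'
#' Columns: \code{timepoint}, \code{tx_mm}, \code{ty_mm}, \code{theta_deg}.
#'
#' @param motion a [rigid_motion()] object.
#' @param path output CSV path.
#' @export
write_motion_csv <- function(motion, path) {
  write.csv(data.frame(timepoint = seq_len(motion$n_timepoints),
                       tx_mm = motion$tx_mm, ty_mm = motion$ty_mm,
                       theta_deg = motion$theta_deg),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a motion trajectory from CSV
#' @param path CSV written by [write_motion_csv()].
#' @return A [rigid_motion()] object.
#' @export
read_motion_csv <- function(path) {
  d <- read.csv(path)
  rigid_motion(d$tx_mm, d$ty_mm, d$theta_deg)
}
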