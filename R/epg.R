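#' EPG fingerprint of a FISP-type MRF sequence
#'
#' Simulates the complex signal evolution of one (T1, T2) tissue under the
#' extended phase graph (EPG) formalism for an inversion-prepared,
#' gradient-spoiled, variable flip angle, fixed-TR sequence. Per TR the
#' magnetization is rotated by \code{fa_scale * FA_n} (constant RF phase),
#' the F0 configuration state is recorded attenuated by \code{exp(-TE/T2)},
#' relaxation/recovery acts over the TR, and a unit gradient-spoiler shift
#' is applied to the F states (no perfect-spoiling assumption). The
#' inversion, when enabled, is an ideal 180 degree pulse not affected by
#' \code{fa_scale}.
#'
#' @param t1_ms,t2_ms relaxation times in ms, both > 0. \code{t2_ms >
#'   t1_ms} is physically unusual but allowed (a warning is emitted).
#' @param seq a [sequence_params()] object.
#' @param fa_scale relative flip-angle scale in (0, 1], e.g. one point of a
#'   slice profile.
#' @param max_states EPG configuration-state truncation order; default
#'   \code{min(n_timepoints, 100)}.
#' @return Complex vector of length \code{seq$n_timepoints}.
#' @examples
#' seq <- sequence_params(rep(30, 10))
#' f <- epg_fisp_signal(1000, 80, seq)
#' @export
epg_fisp_signal <- function(t1_ms, t2_ms, seq, fa_scale = 1,
                            max_states = NULL) {
  check_number(t1_ms, "t1_ms", lower = 1e-9)
  check_number(t2_ms, "t2_ms", lower = 1e-9)
  if (t2_ms > t1_ms)
    warning(sprintf("T2 (%g ms) exceeds T1 (%g ms); simulating anyway", t2_ms, t1_ms))
  check_number(fa_scale, "fa_scale", lower = 1e-12, upper = 1)
  if (!inherits(seq, "sequence_params")) stopf("`seq` must be a sequence_params object")
  if (is.null(max_states)) max_states <- min(seq$n_timepoints, 100L)
  as.vector(cpp_epg_fisp(t1_ms, t2_ms, seq$flip_angles, seq$tr_ms, seq$te_ms,
                         fa_scale, seq$invert, as.integer(max_states)))
}

#' Slice profile for flip-angle averaging
#'
#' Discretizes the excited slice into \code{n_points} positions along the
#' slice-select (frequency) dimension and assigns each a relative flip-angle
#' scale. The default shape is the small-tip Fourier profile of a
#' Hamming-windowed sinc pulse sampled across the slab including its
#' transition bands; \code{shape = "rect"} gives an ideal (uniform) profile
#' and \code{shape = "gaussian"} a Gaussian one. Scales are normalized so
#' their maximum is 1.
#'
#' @param n_points number of sample points across the slice (default 50).
#' @param shape one of \code{"sinc"}, \code{"rect"}, \code{"gaussian"}.
#' @param sinc_lobes half-width of the windowed-sinc pulse in zero crossings.
#' @return An object of class \code{slice_profile} with fields
#'   \code{positions} (dimensionless, spanning the slab) and \code{scale}.
#' @export
slice_profile <- function(n_points = 50, shape = c("sinc", "rect", "gaussian"),
                          sinc_lobes = 3) {
  shape <- match.arg(shape)
  check_number(n_points, "n_points", lower = 1)
  z <- seq(-1, 1, length.out = n_points)
  if (n_points == 1) z <- 0
  scale <- switch(shape,
    rect = rep(1, n_points),
    gaussian = exp(-0.5 * (z / 0.45)^2),
    sinc = {
      # small-tip approximation: profile = FT of the windowed RF envelope
      tt <- seq(-sinc_lobes, sinc_lobes, length.out = 513)
      env <- ifelse(tt == 0, 1, sin(pi * tt) / (pi * tt)) *
        (0.54 + 0.46 * cos(pi * tt / sinc_lobes))
      # z spans the slab plus its transition region
      zs <- z * 0.75
      prof <- vapply(zs, function(f) abs(sum(env * exp(2i * pi * f * tt))), 0)
      prof
    })
  scale <- scale / max(scale)
  structure(list(positions = z, scale = scale), class = "slice_profile")
}

#' EPG fingerprint with slice-profile correction
#'
#' Mean over the slice-profile points of [epg_fisp_signal()] evaluated with
#' \code{fa_scale = profile$scale[i]}.
#'
#' @inheritParams epg_fisp_signal
#' @param profile a [slice_profile()] object.
#' @return Complex vector of length \code{seq$n_timepoints}.
#' @export
epg_with_slice_profile <- function(t1_ms, t2_ms, seq, profile,
                                   max_states = NULL) {
  if (!inherits(profile, "slice_profile")) stopf("`profile` must be a slice_profile")
  if (length(profile$scale) < 1) stopf("empty slice profile")
  check_number(t1_ms, "t1_ms", lower = 1e-9)
  check_number(t2_ms, "t2_ms", lower = 1e-9)
  if (is.null(max_states)) max_states <- min(seq$n_timepoints, 100L)
  as.vector(cpp_epg_fisp(t1_ms, t2_ms, seq$flip_angles, seq$tr_ms, seq$te_ms,
                         pmax(profile$scale, 1e-12), seq$invert,
                         as.integer(max_states)))
}

#' Parse a segmented MATLAB-style grid specification
#'
#' Each segment \code{(start, step, stop)} is enumerated as the inclusive
#' arithmetic sequence \code{start, start + step, ...} not exceeding
#' \code{stop}; segments are concatenated, deduplicated and sorted. This is
#' the notation used for published MRF dictionary grids, e.g.
#' \code{list(c(0, 30, 200), c(200, 10, 600))}.
#'
#' @param spec list of numeric triples \code{c(start, step, stop)}.
#' @return Sorted numeric vector of unique grid values (zeros retained;
#'   [build_dictionary()] drops them).
#' @export
parse_grid <- function(spec) {
  if (!is.list(spec) || length(spec) == 0) stopf("`spec` must be a non-empty list")
  vals <- unlist(lapply(spec, function(s) {
    if (length(s) != 3) stopf("each grid segment must be c(start, step, stop)")
    if (s[2] <= 0) stopf("grid step must be > 0")
    if (s[3] < s[1]) stopf("grid stop %g is below start %g", s[3], s[1])
    seq(s[1], s[3], by = s[2])
  }))
  sort(unique(vals))
}

#' Published dictionary grid specifications
#'
#' T1/T2 grid segments for the standardized-phantom and brain dictionaries,
#' in ms, ready for [parse_grid()].
#' @return A list of segment lists.
#' @export
mrf_dictionary_grids <- function() {
  list(
    phantom = list(
      t1 = list(c(0, 30, 200), c(200, 10, 600), c(600, 20, 1200), c(1200, 30, 1600)),
      t2 = list(c(0, 2, 70), c(70, 10, 120), c(120, 5, 270))),
    brain = list(
      t1 = list(c(0, 10, 800), c(800, 40, 1400), c(1400, 300, 6000)),
      t2 = list(c(0, 5, 100), c(100, 10, 500), c(500, 50, 1000), c(1000, 300, 2600)))
  )
}

#' Build an MRF dictionary over a (T1, T2) grid
#'
#' Simulates one slice-profile-corrected EPG fingerprint per (T1, T2) pair of
#' the Cartesian grid product. Zero relaxation times are dropped (with a
#' message): they are non-physical and would give undefined normalized
#' atoms. Pairs with T2 > T1 are kept by default, mirroring published grids;
#' set \code{exclude_t2_gt_t1 = TRUE} to prune them. Atom ordering is
#' deterministic: T1-major, T2-minor.
#'
#' @param t1_grid,t2_grid numeric vectors of T1/T2 values in ms (e.g. from
#'   [parse_grid()]).
#' @param seq a [sequence_params()] object.
#' @param profile a [slice_profile()] object.
#' @param exclude_t2_gt_t1 drop atoms with T2 > T1.
#' @param max_states EPG truncation order, see [epg_fisp_signal()].
#' @return An object of class \code{mrf_dictionary}: \code{atoms} (complex
#'   Nt x Na), \code{entries} (data.frame with \code{t1_ms}, \code{t2_ms}),
#'   \code{atom_norms}, \code{seq}, \code{profile}.
#' @export
build_dictionary <- function(t1_grid, t2_grid, seq, profile = slice_profile(),
                             exclude_t2_gt_t1 = FALSE, max_states = NULL) {
  t1 <- sort(unique(t1_grid[t1_grid != 0]))
  t2 <- sort(unique(t2_grid[t2_grid != 0]))
  if (length(t1) < length(unique(t1_grid)) || length(t2) < length(unique(t2_grid)))
    message("dropping zero entries from the dictionary grids")
  if (length(t1) == 0 || length(t2) == 0)
    stopf("dictionary grids are empty after zero removal")
  entries <- expand.grid(t2_ms = t2, t1_ms = t1)[, c("t1_ms", "t2_ms")]
  if (exclude_t2_gt_t1) entries <- entries[entries$t2_ms <= entries$t1_ms, ]
  if (is.null(max_states)) max_states <- min(seq$n_timepoints, 100L)
  atoms <- cpp_epg_fisp(entries$t1_ms, entries$t2_ms, seq$flip_angles,
                        seq$tr_ms, seq$te_ms, pmax(profile$scale, 1e-12),
                        seq$invert, as.integer(max_states))
  norms <- sqrt(colSums(Mod(atoms)^2))
  if (any(norms <= 0)) stopf("dictionary contains a zero atom; check the sequence")
  structure(list(atoms = atoms, entries = entries, atom_norms = norms,
                 seq = seq, profile = profile),
            class = "mrf_dictionary")
}

#' @export
print.mrf_dictionary <- function(x, ...) {
  cat(sprintf("<mrf_dictionary> %d atoms x %d time points; T1 %g-%g ms, T2 %g-%g ms\n",
              ncol(x$atoms), nrow(x$atoms), min(x$entries$t1_ms), max(x$entries$t1_ms),
              min(x$entries$t2_ms), max(x$entries$t2_ms)))
  invisible(x)
}

#' Compress a dictionary to a rank-R SVD subspace
#'
#' Computes the first \code{rank} left singular vectors U_R of the Nt x Na
#' atom matrix (via the eigendecomposition of the Nt x Nt Gram matrix, which
#' is cheap for Na >> Nt) and projects the atoms into that subspace. The
#' captured fraction of squared Frobenius norm is reported.
#'
#' @param dict an [build_dictionary()] object.
#' @param rank subspace rank R, \code{1 <= R <= min(Nt, Na)}.
#' @return An object of class \code{compressed_dictionary}: \code{basis}
#'   (Nt x R, orthonormal columns), \code{rank}, \code{compressed_atoms}
#'   (R x Na), \code{energy_fraction}, \code{singular_values}, \code{parent}.
#' @export
compress_dictionary <- function(dict, rank = 10) {
  if (!inherits(dict, "mrf_dictionary")) stopf("`dict` must be an mrf_dictionary")
  nt <- nrow(dict$atoms); na <- ncol(dict$atoms)
  if (rank < 1 || rank > min(nt, na)) stopf("`rank` must be in [1, %d]", min(nt, na))
  gram <- dict$atoms %*% Conj(t(dict$atoms))
  eg <- eigen((gram + Conj(t(gram))) / 2, symmetric = TRUE)
  ev <- pmax(Re(eg$values), 0)
  basis <- eg$vectors[, seq_len(rank), drop = FALSE]
  structure(list(
    basis = basis,
    rank = as.integer(rank),
    compressed_atoms = Conj(t(basis)) %*% dict$atoms,
    energy_fraction = sum(ev[seq_len(rank)]) / sum(ev),
    singular_values = sqrt(ev),
    parent = dict), class = "compressed_dictionary")
}

#' @export
print.compressed_dictionary <- function(x, ...) {
  cat(sprintf("<compressed_dictionary> rank %d, %.4f%% of atom energy captured\n",
              x$rank, 100 * x$energy_fraction))
  invisible(x)
}
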