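Package: mrfmoco
Title: Rigid Motion-Corrected Magnetic Resonance Fingerprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Retrospective rigid-body motion correction for 2D golden-angle
    radial magnetic resonance fingerprinting (MRF). Implements the full
    correction chain: extended-phase-graph (EPG) simulation of FISP-type
    fingerprints with slice-profile correction and SVD dictionary
    compression; golden-angle radial trajectories, Voronoi density
    compensation and a Kaiser-Bessel gridding NUFFT; iterative SENSE
    sliding-window reconstruction of intermediate images; multi-reference
    rigid registration with normalized mutual information; k-space
    correction of the estimated motion by trajectory rotation and phase
    ramps; low-rank (subspace) inversion of the corrected data; and
    inner-product dictionary matching to T1/T2/M0 maps. A digital-phantom
    simulator generates multi-coil radial MRF raw data under programmable
    rigid motion so the whole pipeline can be exercised without scanner
    data. An image-based motion correction (IBMC) baseline is included for
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
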