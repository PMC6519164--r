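# mrfmoco — rigid motion-corrected MR fingerprinting

Magnetic resonance fingerprinting (MRF) estimates quantitative T1/T2/M0
maps from a single transient-state acquisition: the flip angle varies along
a train of ~1750 TRs, one golden-angle radial spoke is acquired per TR, and
each pixel's signal evolution ("fingerprint") is matched against a
dictionary simulated with the extended phase graph (EPG) formalism. Because
the maps combine data from the whole train, head motion during the scan
leaks ghosting and blurring into the maps and biases the matched values.

`mrfmoco` implements a retrospective rigid-motion correction for 2D radial
MRF, aimed at quantitative-MRI researchers and reconstruction developers.
The chain is:

1. **Sliding-window iterative SENSE** intermediate images
   `Î_t = argmin_I ||S F C I − K_t||²` over a moving block of 50 spokes;
2. **multi-reference rigid registration** of the intermediate images with
   normalized mutual information, merged (by exact pose composition) into
   one zero-mean motion trajectory `(t_x(t), t_y(t), θ(t))`;
3. **k-space correction** per spoke: coordinates rotated by `−θ`, samples
   multiplied by the translation phase ramp
   `K′(R_{−θ}k) = K(k)·e^{+2πi k·t}` (magnitude-preserving);
4. **low-rank inversion** `Î = argmin_I ||S U_R F C I − K′||²` over the
   R = 10 singular images of the dictionary SVD basis `U_R`, followed by
   inner-product dictionary matching.

A digital-phantom simulator generates multi-coil radial MRF raw data under
programmable rigid motion (abrupt steps, sinusoids), so the whole pipeline
runs and is validated without scanner data. An image-based motion
correction baseline (IBMC — align the sliding-window images, then match)
is included for comparison. The package is self-contained scientific R
with Rcpp/RcppArmadillo cores (EPG, Kaiser-Bessel gridding NUFFT, CG
solvers, NMI registration).

## Worked example

A desk-scale run of the abrupt-motion experiment (96×96 matrix, 1000 TRs,
4 coils; the motion is an 8 px / 2 px / 12° step at one seventh of the
train):

```r
library(mrfmoco)
cfg <- mrf_config("tiny", matrix = 96, n_samples = 96, n_timepoints = 1000,
                  stride = 10, rank = 10, motion = "abrupt",
                  event_timepoint = 143)
sim   <- mrf_simulate(cfg)            # digital phantom + radial k-space
dicts <- mrf_build_dictionary(cfg)    # EPG dictionary + rank-10 basis
nmc   <- mrf_recon_nmc(sim, dicts)    # low-rank recon, no correction
mc    <- mrf_mcmrf(sim, dicts)        # full motion-corrected pipeline

est <- attr(mc, "motion")
amp <- motion_step_amplitudes(est, cfg$event_timepoint, exclude = cfg$window)
```

This prints (about three minutes on one CPU):

```
recovered step: tx = 8.03 px, ty = 2.01 px, theta = 11.78 deg
NMC     T1 RMSE 1533.0 ms  T2 RMSE  748.8 ms
MC-MRF  T1 RMSE   44.9 ms  T2 RMSE   38.0 ms
```

The registration recovers the programmed step to within a tenth of a pixel
/ a quarter degree, and the corrected reconstruction removes almost all of
the map error that the uncorrected low-rank reconstruction suffers.
`mrf_ibmc()` produces the baseline maps, `mrf_report()` the masked error
metrics (with rigid gauge alignment), `write_maps_nifti()` /
`write_motion_csv()` / `write_mrf_container()` the output files. A thin
command-line driver for the same stages is installed at
`inst/cli/mrfmoco.R` (`Rscript mrfmoco.R simulate|dict|recon-nmc|mcmrf|ibmc|report
--config cfg.yaml`).

The methods vignette (`vignettes/motion-corrected-mrf.Rmd`) documents the
signal model, the registration design (pose composition, interpolation
dither), the numerical choices, and the scaled-down study conditions.

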