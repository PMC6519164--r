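---
title: "Rigid motion-corrected MR fingerprinting: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigid motion-corrected MR fingerprinting: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mrfmoco)
```

# The problem

Magnetic resonance fingerprinting (MRF) varies the flip angle along a long
train of TRs so that every (T1, T2) combination traces a unique transient
signal evolution — a *fingerprint*. One golden-angle radial spoke is
acquired per TR, and per-pixel fingerprints are matched against a simulated
dictionary to produce quantitative T1, T2 and M0 maps. Because the final
maps combine data from the whole train, rigid head motion during the scan
misregisters time points against each other and leaks ghosting and blurring
into the maps.

`mrfmoco` implements a retrospective correction with four stages:

1. **Sliding-window reconstruction** — iterative SENSE on a moving block of
   50 consecutive spokes produces intermediate images with tolerable
   aliasing at ~200 ms temporal resolution (`sliding_window_series()`).
2. **Multi-reference rigid registration** — normalized mutual information
   (NMI) registration of every intermediate image against a set of
   reference images spread over the scan, merged into one zero-mean motion
   trajectory (`estimate_motion_multireference()`).
3. **k-space correction** — each spoke's coordinates are rotated by the
   negated estimated rotation and its samples receive the translation phase
   ramp `exp(+2i pi k . t)`; magnitudes are untouched (`correct_kspace()`).
4. **Low-rank inversion** — conjugate-gradient least squares directly on
   the R = 10 coefficient images of the dictionary's SVD subspace, followed
   by inner-product dictionary matching (`low_rank_inversion()`,
   `match_singular()`).

A digital-phantom simulator (`simulate_mrf_kspace()`) generates multi-coil
radial MRF raw data under programmable rigid motion so that the chain can
be exercised and validated without scanner data. An image-based correction
baseline (IBMC: align the sliding-window images, then match;
`ibmc_pipeline()`) is included for comparison.

# Signal model

Fingerprints are simulated with the extended phase graph (EPG) formalism
for an inversion-prepared, gradient-spoiled (FISP-type), fixed-TR sequence:
per TR an RF rotation by the scheduled flip angle (constant RF phase), the
F0 configuration state recorded attenuated by `exp(-TE/T2)`, relaxation
and Z0 recovery over the TR, and a unit gradient-spoiler shift of the F
states. No perfect-spoiling assumption is made; configuration states are
truncated at order `min(Nt, 100)`. The inversion is an ideal 180° pulse
applied immediately before the first TR. The implementation agrees with an
independent isochromat (Bloch-rotation) simulation to machine precision
(see `test-epg.R`).

Default protocol constants: TE/TR = 1.23/4.3 ms, 1750 time points, flip
angles between 0 and 70°, 160 samples per spoke, 320 mm FOV. The exact
flip-angle waveform of the emulated protocol is not public; the default
generator (`mrf_flip_angle_schedule()`) produces ten sinusoidal half-lobes
with peak amplitudes ramping to 70° plus a small deterministic jitter,
which reproduces the qualitative structure (slow smooth variation, rising
envelope) that gives T1 sensitivity early (near the inversion) and T2
sensitivity at the high-flip-angle lobes. Any schedule can be substituted
(numeric vector or `read_flip_angles_csv()`).

**Slice profile.** The excited slice is discretized into 50 points along
the slice-select dimension; the dictionary fingerprint is the mean of EPG
simulations with the flip angle scaled by the profile. The default profile
is the small-tip Fourier transform of a Hamming-windowed sinc pulse;
rectangular and Gaussian shapes are available. The inversion pulse is not
scaled by the profile.

**Dictionaries.** Grids follow the published segmented notation, e.g.
phantom T1 `[0:30:200, 200:10:600, 600:20:1200, 1200:30:1600]` ms
(`mrf_dictionary_grids()`, `parse_grid()`). Zero relaxation times are
dropped (non-physical, undefined normalized atoms); T2 > T1 pairs are kept
by default to mirror the printed grids, with an exclusion switch.
Compression computes the rank-R left singular basis via the
eigendecomposition of the Nt x Nt Gram matrix, which is much cheaper than
a full SVD when the atom count far exceeds the train length and agrees
with it to numerical precision.

# Encoding model

k-space coordinates are normalized to cycles/pixel in [-0.5, 0.5); the
image/rotation centre and the k-space DC both sit at matrix index N/2.
Spoke angles advance by the 2D golden angle, 111.2461°. The NUFFT is
Kaiser-Bessel gridding with oversampling 2 and kernel width 7 (Beatty
beta), giving ~5e-7 agreement with the direct Fourier sum and an exactly
adjoint forward/adjoint pair. Density compensation uses the closed-form
polar Voronoi cells of radial line sets: because every spoke passes through
DC with uniform radial spacing, each sample's Voronoi cell is a polar wedge
whose area follows from the sorted spoke directions — this is exact for
the trajectories used here (also after motion correction, which only
rotates spokes about DC) and avoids a general computational-geometry
dependency. Weights are recomputed per reconstruction window and after
correction, since rotations change the angular distribution.

Coil sensitivities are an input. The simulator provides deterministic
analytic maps (Gaussian lobes on a ring with a gentle phase);
data-driven calibration is out of scope.

# The simulator and what it does (not) emulate

The brain-like phantom is an ellipse composition with folded (gyri-like)
boundaries and asymmetric internal structure, with white matter T1/T2 =
738/48 ms, gray matter 1127/69 ms, CSF 4000/2000 ms and small inclusions
for resolution assessment. The folded boundary matters: a smooth elliptical
phantom is nearly rotation-symmetric and makes in-plane rotation poorly
identifiable by registration, which real anatomy is not.

Motion enters the forward model per TR (one spoke = one motion state). Two
models are provided:

* `motion_model = "kspace"` (default): spoke n samples the static
  coil-weighted spectrum at coordinates rotated by the motion state, with
  the translation as a phase ramp. This is how motion experiments are
  classically synthesized from a motion-free acquisition, and it is exact:
  correcting with the true trajectory restores the motion-free data to
  machine precision, so round-trip tests isolate the correction itself.
* `motion_model = "image"`: the contrast image is moved in the image domain
  (bilinear interpolation) before coil weighting and sampling. This path
  does not share the correction's k-space motion representation and serves
  as an inverse-crime check, at the cost of interpolation error.

The three standard motion experiments are generated by `motion_abrupt()`
(step of 8 px left-right, 2 px anterior-posterior, 12° at time point 250
or 1500 of 1750) and `motion_sinusoidal()` (same translations, 24°
rotation). Printed amplitudes are peak values and convert to mm via the
pixel size. The sinusoid's frequency is not printed in the emulated
protocol; the default is 3 cycles per scan (period ≈ 583 TRs, an order of
magnitude slower than the sliding window, as deliberate head motion is).
When the train is shortened for desk-scale experiments the step positions
and the cycle count are scaled so the fractional timing and the
window-to-period ratio are preserved.

What the simulator does **not** emulate: through-plane motion (a 2D method
cannot correct it; a slice-content replacement diagnostic is deliberately
out of scope), B0/B1 inhomogeneity, magnetization transfer, and
scanner-specific artifacts. Passing tests therefore demonstrate the
correctness of the correction chain under rigid in-plane motion, not
robustness to everything a real scan contains.

# Registration design

NMI (32 bins, joint histogram over the overlap region) is contrast-robust,
which matters because the intermediate images traverse the inversion
recovery. The optimizer is a 2-level coarse-to-fine search: exhaustive
seeding over ±25% FOV translations and ±30° rotations at a ~32 px pyramid
level, a local grid refinement at ~64 px, and Nelder-Mead polish at full
resolution.

Two numerical details proved load-bearing:

* **Interpolation dither.** Evaluating NMI with the moving image resampled
  only at the candidate pose dents the similarity landscape at grid-aligned
  poses (there the resampling is exact and unsmoothed), which biased
  rotation estimates by 1-3° on streaky sliding-window images. All
  evaluations therefore resample *both* images through a constant,
  slightly off-grid dither pose, making the interpolation smoothing
  pose-independent. Static-data rotation scatter drops from ~1° to ~0.2°.
* **Pose algebra, not parameter arithmetic.** Rigid poses compose; they do
  not add. Registrations against a rotated reference return translations
  expressed in that reference's rotated frame, so averaging raw parameters
  across references aliases translation between the axes (with a 12°
  rotation and an 8 px shift the error exceeds 1 px). The implementation
  converts every registration to an object pose, maps each reference's
  trajectory into the first reference's frame by composing with a robustly
  estimated (median over windows) frame offset, gates disagreeing
  references per window by their NMI score, and averages. The published
  "centre each parameter, then average" recipe is recovered as the final
  *reporting* gauge: the output trajectory has exactly zero mean per
  parameter, and the subtracted means are stored as a gauge offset that
  `correct_kspace()` restores internally — a pose sequence minus a
  parameter constant is no longer a self-consistent sequence of rigid
  poses, and correcting with it measurably blurs the reconstruction.

References default to every 100th sliding-window image. Experiments with
denser reference sets (every 100 *time points* at stride 10) were not
robust: references landing on fast-motion windows are themselves blurred
and degrade every registration against them.

# Reconstruction choices

Both solvers run conjugate gradient on density-weighted normal equations
with zero initialization and a fixed budget of 15 iterations and no
explicit regularization term; the small budget regularizes naturally and
keeps results deterministic. The Voronoi weights enter as the
data-consistency weighting, the standard combination that makes 15
iterations sufficient for reconstruction-quality solutions. Note that 15
iterations do *not* reach the exact least-squares optimum of small
ill-conditioned test systems; operator-equivalence tests against dense
solvers therefore run CG to convergence, while reconstruction tests use
the 15-iteration protocol.

Matching runs in the compressed domain (rank-R inner products; equivalent
to time-domain matching because the basis is orthonormal) with brute-force
argmax over atoms, ties to the lowest index. M0 is
`|<c, s>| / ||c||^2`; the match correlation is stored per pixel.

# Evaluation methodology

`mrf_report()` compares parametric maps against ground truth. Maps from
different pipelines live in different rigid frames (the corrected
reconstruction sits in the zero-mean pose frame, the image-based baseline
in the first window's pose), and a map is in any case only defined up to a
rigid gauge. The report therefore aligns the estimated maps to the truth
frame first — NMI registration of M0 seeds a direct search that minimizes
the masked relative error itself — resampling the piecewise-constant T1/T2
maps with nearest-neighbour interpolation (bilinear would fabricate
relaxation values at tissue borders). Errors are then masked RMSE/MAE in
ms and relative (%) form, over the object mask eroded by a configurable
number of pixels (default 2; the ordering experiments in the acceptance
suite use the full mask, erosion 0).

# Scaled-down study conditions

The full protocol (matrix 160, 1750 spokes, stride-1 windows, 12 coils)
takes hours on a workstation; the packaged experiments use documented
scaled-down configurations chosen once:

* **Motion recovery (abrupt and sinusoidal experiments):** matrix 128,
  full 1750-TR train, 4 coils, window 50, stride 10, references every 100
  windows — a few minutes each.
* **Method ordering (no correction vs image-based vs k-space corrected):**
  matrix 96, 1000-TR train, the published brain dictionary grids (~8000
  atoms), rank 10; the two step positions sit at the same fractions of the
  train (250/1750, 1500/1750) and the sinusoid keeps the full-scale
  window-to-period ratio (2 cycles per 1000 TRs).
* **Null tests:** matrix 64-96; the vial phantom uses grid-aligned values
  and the published phantom grids, and exactness is asserted on the modal
  matched value over each eroded vial interior (a single centre pixel can
  flip by one grid step from residual aliasing).

# Known limitations

* Motion estimates have the sliding window's ~200 ms temporal resolution;
  abrupt motion inside one window cannot be resolved, and estimates within
  ±window of a discontinuity are unreliable (they are excluded from the
  step-amplitude readout).
* On the late-step experiment the no-correction maps are barely corrupted
  (motion that late affects mainly the last, T2-encoding part of the
  train); the image-based baseline's interpolation blur can then exceed
  the motion damage itself, so "any correction is better than none" does
  not hold there. The k-space corrected reconstruction remains the best of
  the three in all experiments.
* Correction assumes the coil sensitivities move with the object (the
  standard retrospective approximation); for the large smooth simulated
  coils the residual inconsistency is negligible.
* T2 accuracy inherits the protocol's known weaknesses (short train, no
  B1 correction); the coarse upper dictionary segments dominate absolute
  CSF errors.
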