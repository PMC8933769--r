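---
title: "Amyloid PET quantification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amyloid PET quantification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(amypet)
```

This vignette documents the scientific model behind `amypet`, the
parameters a user may want to touch, the assumptions baked into the
synthetic fixtures, and the places where the design was genuinely open and
a choice had to be made.

## The two processes

### Centiloid quantification

Amyloid PET SUVR values depend on the tracer, the reference region and the
processing chain. The Centiloid scale removes that dependence by a
tracer-specific linear map anchored at 0 (mean of young amyloid-negative
controls) and 100 (typical Alzheimer-level burden). The chain is:

1. *Reorientation*: `set_origin()` translates the affine so a chosen voxel
   (conventionally the anterior commissure) is world (0,0,0). Data are
   never resampled at this step.
2. *Coregistration*: `register_linear()` maximizes normalized mutual
   information, NMI = (H(A)+H(B))/H(A,B), over rigid (PET→MRI) or affine
   (MRI→template fallback) parameters.
3. *Spatial standardization*: nonlinear warps are consumed, not estimated —
   `apply_deformation()` applies an externally computed displacement field
   (5-D NIfTI, mm units, pull-back convention). Segmentation-based
   normalization is a research field of its own and is deliberately out of
   scope; the affine fallback is adequate for the phantom geometry used in
   testing.
4. *SUVR and CL*: `compute_suvr()` takes the unweighted mean over the
   target VOI divided by the reference-VOI mean; `suvr_to_centiloid()`
   applies the published linear coefficients, shipped as a versioned CSV
   (`inst/extdata/centiloid_calibration.csv`) holding exactly the 14
   published (tracer, reference) pairs. The 6 unpublished pairs raise an
   explicit error rather than extrapolating.

`validate_against_reference()` regresses computed on reference CL
(computed = a + b·reference — note the orientation, so a slope below 1
means the pipeline under-reads high-burden scans) and applies the standard
acceptance bands: b ∈ [0.98, 1.02], |a| ≤ 2 CL, R² > 0.98.

CL values are stored unrounded; rounding is a display concern.

### Z-score mapping

A subject's standardized PET is smoothed, normalized by its reference-VOI
mean, and compared voxelwise with a normative database:

Z = (subject − mean of controls) / SD of controls.

Key decisions, in processing order:

* **Smoothing**: "8 mm kernel" is interpreted as 8 mm FWHM isotropic (the
  standard neuroimaging convention), σ = FWHM/(2√(2 ln 2)) per axis in
  voxel units, separable convolution, zero-padded edges, kernel truncated
  at 4σ and renormalized. FWHM is a parameter (`fwhm_mm`, default 8).
* **Normalization before masking**: the analysis mask (target VOI minus a
  user-supplied white-matter mask; white matter carries high nonspecific
  counts) is applied at statistics time. Data are never zeroed in place.
  The exact derivation of the WM mask is left to the user; the synthetic
  fixtures ship a geometric one.
* **Database**: controls must have global CL below `cl_threshold`
  (default 10, the published optimum for excluding neuritic plaques);
  exclusions are logged, not silent. The SD uses the n−1 denominator — at
  the realistic smallest database size (n = 10) this is material, so the
  choice is recorded in the DB metadata. Provenance (tracer, reference,
  FWHM) is stored with the database and *enforced* when a subject map is
  computed: a subject smoothed or normalized differently from the DB is an
  error, not a warning.
* **SD floor**: voxels with near-zero control SD (below 1e-6 × the mean SD
  over the mask) are excluded from the mask and counted, never clamped —
  clamping manufactures arbitrary Z values.
* **Thresholding**: suprathreshold means Z ≥ `z_threshold` (default 2.6,
  one-sided p < 0.01) in connected components of at least `min_voxels`
  (default 300 voxels = 2.4 cc on the 2 mm grid) under `connectivity`
  (default 18; the convention is not universal, so it is configurable).
  Testing is one-sided positive: amyloid accumulation is an increase, and
  negative Z is rendered but never drives positivity.
* **Regional calls**: a region is positive iff ≥ 1 voxel of ≥ 1 surviving
  cluster lies in its mask. Overlap counts are reported so borderline
  calls are auditable.

### Agreement and cutoff statistics

`chi_square_2x2()` is the Pearson statistic *without* continuity
correction (the uncorrected form is what published tracer-agreement tables
reproduce; Yates-corrected values do not match them). Degenerate tables
(a zero row or column margin) return statistic 0 with a flag.

`roc_analysis()` sweeps thresholds over midpoints of sorted unique scores
plus ±∞, computes the trapezoidal AUC (identical to the Mann–Whitney rank
form, ties counted ½), and picks the operating cutoff by **maximum
accuracy** (TP+TN)/N — the "most accurate detection" rule — with ties
broken toward the lowest cutoff so a run of equally accurate thresholds
reports the most sensitive one. Youden's J is available via `rule =
"youden"` for users who prefer it.

## Registration internals

No installed registration engine was available to delegate to, so the
linear registration is implemented here:

* NMI on a 64×64 joint histogram over the 1st–99th intensity percentiles
  of each image; samples falling outside the moving image are excluded.
* Multi-resolution (default 4 mm → 2 mm, expressed relative to the image's
  own resolution in the test fixtures), with anti-aliasing smoothing
  before downsampling.
* Optimization is derivative-free: cyclic per-parameter golden-section
  line searches with shrinking brackets, plus two additions that proved
  necessary in practice and are part of the design: a **joint
  uniform-scale line search** for affine fits (per-axis scale moves barely
  change NMI on their own, so a pure coordinate scheme stalls), and a
  **Nelder–Mead polish** at each level (translation/rotation/scale trade
  off against each other near the optimum). Three seeded random restarts
  at the coarsest level guard against poor basins; everything is
  deterministic given `opts$seed` (default 0).
* The NMI sample points carry a fixed, seeded sub-voxel jitter. Without
  it, NMI spikes whenever the candidate transform aligns the grids exactly
  (interpolation becomes exact and the joint histogram artificially
  sharpens), which traps the optimizer at identity-like poses. The jitter
  removes the artifact at the cost of a slightly noisier objective.

On noiseless phantoms this recovers randomized rigid poses (≤ 10 mm,
≤ 10°) to better than 0.2 mm / 0.2° and a 5% global scale to < 1%.

## The synthetic fixtures

`make_voi_set()` builds a geometric template family: an ellipsoidal
cerebrum whose outer shell (normalized radius 0.62–1.0) is the cortical
target, partitioned into four angular sectors (posterior-medial =
posterior cingulate/precuneus, anterior = frontal, inferior = temporal,
remainder = parietal) plus two deep striatal nuclei; an ellipsoidal
cerebellum (whole + gray shell), pons and brainstem as reference regions
(mutually disjoint and excluded from the cerebrum, as in the real
templates); and a deep white-matter compartment. All structural invariants
of real VOI sets — one grid, non-empty, disjoint regions contained in the
target — hold by construction and are asserted.

The shell is deliberately thicker than human cortex and the cerebellum is
sized to a realistic volume fraction. Both choices are driven by the
statistics the fixtures must support: a 600-voxel compact lesion has to
fit inside one cortical region, and a too-small reference VOI turns
reference-mean estimation noise into global Z-map offsets that no real
pipeline (with its ~130 cc cerebellum) would see.

`make_phantom()` is piecewise-constant uptake per compartment, optionally
blurred by a Gaussian scanner PSF (default 4 mm in cohorts) and degraded
by additive white Gaussian noise (SD relative to background, default 0.05
in cohorts). Ground-truth SUVR comes from the pre-blur piecewise values,
so a noiseless, blur-free phantom must be recovered exactly — that is the
basis of the end-to-end validation test, which runs 20 such phantoms
across true SUVR 1.0–2.2 and applies the Centiloid acceptance bands to
computed-vs-truth CL.

`make_cohort()` draws controls i.i.d. around an amyloid-negative template
(gray matter 1.0, hot white matter 1.6) and adds compact lesions to
patients. Lesion amplitudes are expressed in **post-smoothing control-SD
units**: the requested effect is divided by the smoothing kernel's mean
attenuation over the lesion support (computed by smoothing the lesion
indicator once), because a raw pre-smoothing injection of k·SD would read
only ~0.6·k on the final Z map and silently under-deliver the stated
effect. The per-voxel post-smoothing SD itself is known analytically
(white noise through a separable kernel shrinks by √Σw² per axis).

What the fixtures do *not* model: attenuation, scatter, reconstruction
physics, anatomical variability, MRI contrast (registration tests use a
contrast-shifted phantom). Passing tests therefore demonstrate the
correctness of the quantification and statistics chain, not robustness to
real-world acquisition artifacts.

## Numerical conventions

* World convention RAS+, voxel indices 0-based, affines map voxel index →
  mm. The default analysis grid is the common 2 mm MNI-style 91×109×91
  grid (one voxel = 8 mm³, 300 voxels = 2.4 cc).
* Masks resample only with nearest-neighbour and binarize at 0.5
  (templates are probabilistic at the edges in some distributions).
* NaN/Inf voxels in input files are an error, never silently zeroed —
  silent zeros corrupt VOI means downstream.
* Out-of-field voxels become 0 in image resampling but are *excluded*
  (not zero-filled) in registration cost evaluation.
* Cluster ordering is deterministic: size desc, then peak Z desc, then
  lexicographic centroid.

## Problem sizes used in the shipped tests

The test suite and the acceptance script run entirely on generated data:
VOI geometry on 40³–64³ grids at 2 mm; the Klunk-style validation on
twenty 48³ phantoms; the detection study on a 64³ 2 mm grid with an n=30
database and 100 simulated subjects per arm; registration recovery on 40³
phantoms at 4 mm resolution. These sizes were chosen so the full suite
exercises every code path at meaningful statistical power while remaining
comfortable to run on a laptop.

## Known limitations

* Nonlinear spatial normalization is consumed, never estimated; with
  neither a deformation field nor a template, only `--skip-registration`
  inputs can be processed.
* The white-matter mask contract is "user-supplied"; no tissue
  segmentation is provided.
* Only global-scale intensity handling: no partial-volume correction.
* ROC confidence intervals and paired (McNemar-style) tracer comparisons
  are out of scope; the χ² comparison treats the two tracer rows as
  independent samples, matching the published analyses it reproduces.
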