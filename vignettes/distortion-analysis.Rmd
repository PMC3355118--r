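---
title: "Quantifying geometric distortion between paired MR acquisitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying geometric distortion between paired MR acquisitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warpgauge)
```

## The problem

Ultra-high-field (7 T) MRI offers contrast and resolution that make deep
brain structures such as the subthalamic nucleus directly visible, but
stereotactic surgery planning is only safe if the geometry of those
images can be trusted. Geometric distortion has two sources: system-level
effects (gradient nonlinearity, B0 inhomogeneity, imperfect shimming),
which are well approximated at first order by an affine transform —
scaling and shear on top of a rigid repositioning — and subject-dependent
susceptibility effects near tissue–air interfaces, which produce
localized nonlinear displacement together with signal loss and which grow
with field strength.

warpgauge implements an assessment pipeline built on that decomposition.
A "test" acquisition (the 7 T analogue) is registered to a "reference"
acquisition (the 1.5 T clinical analogue) of the same head with a staged,
landmark-free affine registration driven by mutual information. Three
complementary read-outs follow:

1. **Transform decomposition.** The recovered world-mm affine is factored
   uniquely into rotation × scales × unit-triangular shear. The
   distortion metrics are the maximum scaling deviation from 1
   (`max_scale_dev`), the maximum absolute shear tangent (`max_skew`,
   the tangent of the skew angle) and the deviation of the determinant
   from 1 (`volume_dev`). A rigid transform carries no distortion;
   scaling is a weak, correctable form; shear is genuine geometric
   distortion.
2. **Landmark validation.** Named anatomical landmarks placed
   independently on both images are held out of the registration; mapping
   the test-image landmarks through the recovered transform and
   measuring 3D Euclidean distances to their reference counterparts
   gives the target registration error, summarized as boxplot statistics
   and in voxel-equivalent units.
3. **Regional mapping.** The brain bounding box is parceled into 3 × 3
   sub-regions (or 3 slabs for thin acquisitions), each region is
   re-registered seeded by the global transform, and the decomposition
   metrics of the composed per-region transforms form a first-order
   spatial map of distortion. Regions dominated by signal loss are
   excluded — no meaningful estimate is possible there.

Because no public data accompany this design, a digital phantom with
fully known ground truth stands in for the patient pair, and every stage
is validated by parameter recovery rather than by comparison with any
specific external tool.

## The phantom and what it does (and does not) emulate

`generate_phantom()` rasterizes a brain-analog ellipsoid containing
fourteen asymmetric internal structures (ventricle analogues, thalamic
and midbrain blocks, and cortical-marker blobs distributed so that no
sub-region of the brain is structureless) on a 160 mm field of view; the default
64-voxel grid (2.5 mm) is a reduced-scale stand-in for a 256-voxel 1 mm
clinical matrix and keeps simulated registrations fast. The structure
centres double as analytic landmarks, mirroring the handful of
anatomically unambiguous points (AC, PC, aqueduct, chiasm, infundibulum)
a neurosurgeon would mark.

Intensities are not piecewise-constant: a fixed-phase sum of
low-frequency cosines (wavelengths 40–80 mm, relative amplitude 0.15 by
default) modulates every structure. This matters more than it may
appear. On exactly piecewise-constant synthetic images, histogram-based
similarity measures develop artifact optima — sub-voxel lattice effects
worth hundredths of a bit — that have no counterpart in real tissue;
mild smooth texture restores the local intensity gradients real images
possess.

`apply_ground_truth_distortion()` builds the test image through the
ground-truth mapping `m(y) = A(y + d(y))`, where `A` is the affine built
from 12 parameters and `d` is a Gaussian-bump displacement
(amplitude × exp(−r²/2σ²)) centred on a simulated air cavity — a
one-parameter stand-in for susceptibility warping, whose true spatial
form the affine pipeline does not attempt to model. The same σ sets the
radius of the co-located signal-dropout sphere, since both degradations
share the same physical source; the dropout profile is
`1 − strength · exp(−(r²/2σ²)^order)`, a plain Gaussian shoulder at the
default order 1 and, at higher orders, the flat-core sharp-edged signal
void that air cavities actually produce (a plain Gaussian at full
strength suppresses signal below detection thresholds only within
~0.46 σ, far too little to blank a region). On top come a polynomial
multiplicative bias field (`exp` of a seeded random polynomial scaled to
a maximum log-magnitude) and Rician noise (`|(I + n₁) + i n₂|`,
`n ~ N(0, σ²)`), the standard magnitude-MR noise model; the preset SNR
of ~20 (σ = 5 against a base intensity of 100) is typical of clinical
T1 acquisitions.

Two conventions deserve emphasis:

* The mapping direction is chosen so that `A` is *exactly* the matrix a
  moving-to-fixed registration must recover: the test volume is the
  pull-back of the reference field through `m`. Test-space landmarks are
  obtained by inverting `m` by fixed-point iteration to machine
  precision, so landmark pairs satisfy the recorded mapping to well
  below 1e-9 mm before any jitter is applied.
* When the phantom spec is passed to the generator, the test image is
  rasterized *analytically* at the mapped points rather than by
  interpolating the reference volume. Interpolated generation leaves the
  test image systematically blurrier than the reference, an asymmetry
  real scanner pairs do not have, and one that measurably displaces
  intensity-based cost optima (it was worth ~1 mm in regional fits
  during development). The analytic path is therefore the standard study
  condition.

What the phantom does not emulate: anatomy (no template brains), pulse
sequences or k-space effects, motion, or the true spatial structure of
susceptibility fields. Passing recovery tests here demonstrates that the
pipeline's algebra, optimization and statistics are correct at realistic
magnitudes — not that any particular clinical dataset would yield the
same numbers.

## Registration design

`register()` follows a staged schedule. At the coarsest level of a
Gaussian pyramid (3 dyadic levels by default), a rotational grid search
(default ±30° per axis at 3° steps, the conventional coarse search
resolution) is run with the translation initialized by centre-of-mass
alignment for each rotation candidate; the best candidates are refined
by a derivative-free simplex at 6 DOF through the pyramid; for 12 DOF,
scales and shears are released at the two finest levels, followed by
polish restarts until the cost gain drops below `convergence_tol`
(10⁻⁵ bits). Rotations act about the fixed-volume centre and are
composed extrinsically z·y·x — stated explicitly because the
decomposition must invert the same convention.

The cost is mutual information in bits from a joint histogram (64 bins,
linear soft assignment) over fixed-voxel samples restricted to the brain
mask, with intensity ranges clipped to the 2nd–98th percentiles so
dropout and hyperintense tails do not waste bins; correlation ratio is
available as a fallback. Three numerical choices matter:

* **Jittered sampling.** Cost samples are taken at seeded uniformly
  jittered sub-voxel positions (fixed intensities interpolated there),
  never at voxel centres. Grid-commensurate transforms otherwise look
  spuriously sharp because trilinear interpolation smooths everywhere
  except on the grid — the classic MI interpolation artifact.
* **Adaptive oversampling.** When a level or region has few masked
  voxels, each is sampled several times with independent jitter (up to
  8×, targeting ~20k samples) to keep the MI estimate stable.
* **Monotonicity guarantee.** The final transform is never returned if
  it scores below the initialization at the finest level; the
  initialization is returned instead.

Out-of-overlap samples are dropped; if fewer than a minimum overlap
remain the cost raises an overlap error, which the optimizer treats as a
penalty and callers see as a diverged transform.

## Regional registration and its robustness problem

Each region's fixed crop is registered at 12 DOF directly against the
full moving volume, initialized at the global transform, with tight
bounds (|scale−1| and |shear| ≤ 0.1, ≤ 10 mm / 10°) around it. Working
on the total transform keeps the optimized cost on the same
single-interpolation path as the acceptance measure; registering against
a cropped or pre-resampled moving copy proved to be a mistake twice over
— samples leaving a small moving field of view shrink the overlap and
fake improvements, and a doubly-resampled copy carries extra blur that
shifts the optimum. Crops are taken with a 4-voxel margin (sampling mask
kept strictly to the region) so that pyramid smoothing of the crop sees
the same spatial context as the full moving volume.

Sub-volumes contain an order of magnitude fewer samples than the whole
brain, and *any* single intensity estimator then has artifact optima
within ~1 mm and ~0.01 scale of the truth. The success criterion — a
local result counts only if it improves on the global registration for
that area — is therefore judged by two differently-constructed
estimators that must agree: the plain voxel-centre MI, and a
blur-symmetric MI in which both volumes are pre-smoothed by one voxel so
interpolation blur cannot be exploited. Both judges must improve by
more than a practical-significance floor of 0.002 bits. During
development each judge alone accepted a different subset of spurious
sub-millimetre "improvements" (gains up to ~0.008 bits on one judge but
≤ 0.0004 on the other); their intersection with the floor accepted
none, while genuine region-scale warps clear both by an order of
magnitude. When the criterion is not met, the global
transform is retained for that region (local = identity, `improved =
FALSE`) — matching the observation that central regions need essentially
no correction.

Fallbacks (correlation-ratio cost, restricted search range, perturbed
initializations) engage only when an attempt *fails* — errors or leaves
the region clearly worse (0.01 bits) than the global fit. An attempt
that converges without significant improvement is a conclusion, not a
failure, and triggers no retry: retrying until some attempt happens to
pass the judges would reintroduce exactly the selection effect the
dual-judge criterion exists to prevent.

Regions whose globally-aligned test image holds signal in fewer than
half of the in-mask voxels (threshold: 10% of the robust maximum) are
excluded before registration, emulating the inferior regions near air
cavities where signal loss makes distortion estimation meaningless.

## Other numerical choices and degenerate inputs

* **Bias correction** estimates the field as the masked
  Gaussian-smoothed log intensity (σ = 25 mm default; numerator and mask
  smoothed separately and divided, so background never bleeds in), run
  for two passes because the second cancels most of the residual the
  mask boundary leaves after the first; the mask mean is preserved
  exactly. This is a deliberately simple estimator serving the same
  pre-registration role as tissue-model-based tools.
* **Brain extraction** is Otsu threshold → largest 6-connected
  component → morphological closing (ball radius 2) → hole fill. It is
  scale-invariant by construction, and its accuracy is judged by Dice
  against the phantom's analytic support, not by equivalence with any
  surface-based tool.
* **Boxplot convention** for landmark distances: quartiles by linear
  interpolation of order statistics (type 7), whiskers at the most
  extreme datum within 1.5 IQR, outliers beyond. (Some published
  captions say "quintile" where quartile is clearly meant; the
  convention here is explicit and the multiplier configurable.)
  Voxel-equivalent distances are computed against the reference voxel
  size, and per-axis errors against per-axis voxel sizes, because on
  anisotropic slabs the meaningful unit is the in-plane voxel in-plane
  and the slice thickness through-plane.
* **Decomposition** factors the 3×3 world-mm block as R·S·H by QR with
  sign fixing; reflections (negative determinant) are rejected as
  pathological registrations. Exactly three shear tangents (xy, xz, yz)
  are reported; shear values are order-dependent, and the
  rotation–scale–shear order used here is stated precisely so the
  numbers are interpretable.
* **Degenerate inputs** raise typed errors: all-zero volumes
  ("no-signal"), constant moving images for CR ("degenerate"),
  reflections, singular transforms, empty landmark matches, regions
  outside the volume, masks too thin to split into thirds, and warps
  whose displacement gradient reaches 1 (non-invertible).

## Problem sizes and what the tests compute

The test-suite and the acceptance script run entirely on simulated
conditions chosen once: a 64³ (2.5 mm) phantom for global recovery and
regional mapping; a 160×160×20 slab at 1×1×2 mm for the anisotropic
path; 48³ for the signal-loss scenario; 32–48³ for unit tests. Distortion
magnitudes target the regime reported for 7 T/1.5 T co-registration —
rigid offsets of a few mm and degrees, scales within 1%, shear tangents
up to 0.01, landmark marking error 0.5 mm, SNR ≈ 20 — and the recovery
tolerances (0.3 mm / 0.3°, 0.005 on scale and skew metrics, one voxel on
landmark error) reflect what those conditions support. The
marking-error simulation compares the observed mean landmark distance
under independent 0.5 mm jitter of both sets against the closed
Monte-Carlo prediction for |N(0, 2σ²I₃)|.

## Known limitations

* The Gaussian-bump warp is a stand-in; nothing here infers the true
  spatial form of susceptibility fields, and the pipeline's affine
  read-out only ever captures a warp's first-order (per-region affine)
  projection.
* Regional estimates on structure-poor shell regions remain
  fundamentally less determined than central ones; the dual-judge
  criterion prevents false corrections but cannot create information
  that a nearly-uniform sub-volume does not contain. This mirrors the
  robustness loss that motivates the fallback strategies in practice.
* The registration is deliberately conventional (affine, MI,
  derivative-free); no claim of optimality is made, and nonlinear
  registration is out of scope.
* Phantom realism ends at geometry, texture, bias and Rician noise;
  transfer of the quantitative tolerances to clinical data is an
  empirical question the package cannot answer by itself.
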