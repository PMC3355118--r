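# warpgauge

Quantifies geometric distortion between two MR acquisitions of the same
brain — typically an ultra-high-field (7 T) scan registered to the
clinical (1.5 T) planning scan whose geometry stereotactic surgery
trusts. The question it answers: *how much non-rigid correction does the
high-field image need, and where?*

The method is deliberately the conventional clinical one. After bias
correction and brain extraction, the test image is registered to the
reference with a staged, landmark-free affine registration maximizing
mutual information (coarse rotational search at 3° resolution, 6-DOF
refinement through a multi-resolution pyramid, then 12 DOF releasing
scales and shears). The recovered world-mm transform `A` is decomposed
uniquely as

```
A₃ₓ₃ = R · diag(s₁, s₂, s₃) · H,     H unit-upper-triangular
```

with `R` a rotation; distortion is then read off as

* `max_scale_dev = max |sᵢ − 1|` — maximum scaling change,
* `max_skew = max |Hᵢⱼ|` — maximum skew, the tangent of the skew angle,
* `volume_dev = |det A₃ₓ₃ − 1|` — volume change.

A rigid transform scores zero on all three; shear is the component that
must be regarded as true geometric distortion. Validation is by held-out
anatomical landmarks (target registration error with boxplot statistics,
in mm and in voxel units), and a piecewise pass — nine sub-regions for
whole-head volumes, three slabs for thin anisotropic acquisitions —
re-registers each region seeded by the global transform to map the
spatial distribution of distortion, excluding regions lost to
susceptibility signal dropout.

Because suitable paired patient scans are not publicly available, the
package ships a digital head phantom with fully parameterized ground
truth (affine distortion, localized susceptibility-like warp and
dropout, polynomial bias field, Rician noise), so every stage is
verifiable by parameter recovery. See the vignette
(`vignettes/distortion-analysis.Rmd`) for the model details and design
decisions.

## Worked example

```r
library(warpgauge)

## simulated study pair: reference phantom + distorted "7 T" test image
spec <- default_phantom_spec(64)           # 2.5 mm grid, 160 mm FOV
ph   <- generate_phantom(spec)
ds   <- distortion_spec(translation_mm = c(2, -1.5, 1),
                        rotation_deg   = c(1.5, -1, 2),
                        scales = c(1.01, 0.99, 1.004),
                        shears = c(0.01, -0.006, 0.008),
                        noise_sigma = 5)   # SNR ~ 20
pair <- apply_ground_truth_distortion(ph$volume, ph$landmarks, ds,
                                      seed = 1, spec = spec)

mask <- extract_brain(ph$volume)$mask
fit  <- register(ph$volume, pair$volume,
                 registration_config(dof = 12), fixed_mask = mask)
decompose_affine(fit$transform)
```

```
<decomposition_report>
  translation (mm):  2.0264, -1.5075, 0.98941
  rotation (deg):    1.5781, -1.0878, 2.1419
  scales:            1.0074, 0.988803, 1.00328
  shear tangents:    0.0114616, -0.00578465, 0.0102106
  determinant:       0.9993826
  max scale dev:     0.0111969
  max skew:          0.0114616
  volume dev:        0.000617407
```

The applied distortion metrics (max scale deviation 0.01, max skew
0.01) are recovered to about a part in a thousand despite SNR-20 noise.
Landmark validation against the held-out ground-truth pairs:

```r
mapped <- transform_points(fit$transform, pair$truth$landmarks_test)
landmark_distances(pair$truth$landmarks_ref, mapped,
                   ref_voxel_mm = voxel_size(ph$volume))
```

```
<distance_stats> n = 14
  mean 0.09569 mm, median 0.1021 mm, Q1 0.07247, Q3 0.1127
  outliers: temporal_l 0.1885
```

— every landmark maps well inside one 2.5 mm voxel, the scale at which
registration error is conventionally judged. The regional pass
(`parcel()`, `register_regions()`, `regional_summary()`) produces the
per-region distortion table, and `run_pipeline()` orchestrates the whole
workflow from NIfTI inputs to a JSON report with edge-overlay QC images.

(Numbers above are from `seed = 1` on this package's simulator; they
vary at the last digits with seed.)

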