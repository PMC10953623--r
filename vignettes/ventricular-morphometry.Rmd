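---
title: "Deformation-free ventricular morphometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformation-free ventricular morphometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Behavioural variant frontotemporal dementia (bvFTD) is frequently confused
with primary psychiatric disorders (PPD): both present with apathy,
disinhibition and personality change, and early-stage MRI can look
unremarkable on visual review. The lateral ventricles, however, enlarge in
a characteristic pattern as frontal and temporal tissue is lost —
disproportionately in their *anterior* portions — and ventricular CSF is
one of the most reliably segmentable structures on T1-weighted images.
`ventmorph` implements a screening pipeline built on that observation: it
segments the lateral ventricles, summarizes their shape in a handful of
deformation-free features, and classifies each subject as *compatible* or
*not compatible* with bvFTD using a linear support-vector machine.

The package processes a comma-separated subject table (image path, age,
sex per subject) and produces, per subject, a preprocessed template-space
image, a ventricle segmentation with a voxelwise confidence map, a QC
record, and one row in a feature table carrying the extracted features and
the diagnosis call.

## Pipeline and model

### Stereotaxic normalization

Each native image is intensity-normalized and affinely registered to a
stereotaxic template. Normalization divides out a low-order (degree ≤ 2)
multiplicative polynomial bias field fitted on the log-intensities of
voxels near the modal brain intensity (so one tissue class dominates the
regression), then clamps at the 0.1/99.9 percentiles and rescales to
[0, 100]. The registration maximizes normalized cross-correlation over a
6/9/12-parameter world transform (translations, Euler rotations,
log-scales, shears; default 12), coarse-to-fine over a 3-level pyramid
with 200 Nelder–Mead iterations per level (tolerance 1e-5 on the relative
metric change). Initialization uses intensity centre-of-mass translation
and moment-based per-axis scale estimates, which is what makes the
simplex refinement reliable for scale changes of ±10%. When the finest
level hits its iteration cap, a short restart tests stationarity before
the transform is flagged low-confidence.

Subject intracranial volume (ICV) is estimated as the template ICV mask
volume divided by `scaleDet`, the absolute determinant of the transform's
linear part — i.e. the volume of the back-projected template ICV mask.
This avoids a separate skull-stripping stage, and every downstream
ICV-normalized quantity is invariant to the registration scaling:
template-space volumes are divided by `scaleDet` to native mm³ before use.

### Patch-based label fusion

Segmentation uses weighted voting over a library of labelled examples on
the template grid. For a voxel `x` inside the candidate mask (the union
of library labels dilated by a Euclidean ball, default radius 3 voxels),
every library patch within a search window (default 9³) is compared
against the 3³ patch around `x`:

* **Preselection.** A patch enters the vote only if its
  luminance–contrast structural similarity to the target patch —
  `(2·µ1µ2 / (µ1²+µ2²)) · (2·σ1σ2 / (σ1²+σ2²))`, with a 1e-6 stabilizer
  in each fraction — is at least 0.95. Patch means and standard
  deviations are computed over each patch's own in-bounds voxels.
* **Weights.** Surviving patches are weighted
  `w_i = exp(−d_i / h²)` where `d_i` is the squared intensity distance
  over the offsets in-bounds for both patches, and the adaptive bandwidth
  is `h² = min_i d_i + ε` (ε = 1e-4). The best match therefore always
  receives weight ≈ 1 and dominates when it is much closer than the rest.
* **Vote.** The fused vote is the weighted mean of the library
  centre-voxel labels; the voxel is foreground when the vote reaches the
  decision threshold (default 0.5, ties counting as foreground — a fixed
  deterministic rule). If preselection rejects every patch, the vote
  falls back to the unweighted mean of the window's centre labels.

Voxels outside the candidate mask are background with confidence 0. The
candidate-mask restriction is what keeps the search tractable; it is
justified because ventricles are spatially consistent after affine
registration, and the library is constructed to span the anatomical range
(below). The implementation is exact — the test suite checks it
voxel-for-voxel against an exhaustive brute-force reimplementation on
small volumes.

### Ventricular features

From the binary segmentation the package derives, per subject:

* `total_vv_norm` — total ventricle volume / ICV (dimensionless, not
  log-transformed; only the ratios below are log-transformed).
* `apr_log` — log of the anterior–posterior ratio. A voxel is *anterior*
  iff its centre's world y-coordinate is strictly greater than −12 mm in
  template space; the strict-inequality convention at the plane is fixed
  for determinism. Anterior and posterior volumes partition the mask
  exactly.
* `lr_frontal_log`, `lr_temporal_log` — log left/right volume ratios of
  the frontal and temporal compartments of an 8-compartment lobar atlas
  (frontal / parietal / temporal / occipital × hemisphere). Mask voxels
  falling on background atlas codes are assigned to the nearest labelled
  compartment by iterative 6-neighbour propagation (exact nearest
  assignment on the isotropic template grid up to tie-breaking, which is
  fixed by axis order).

The classifier consumes `(apr_log, total_vv_norm, lr_frontal_log,
lr_temporal_log, age, sex)` in this fixed order, with sex coded male = 1,
female = 0 (the encoding is recorded in the model file).

### Automated quality control

Visual QC is replaced by four explicit checks, each with configurable
thresholds: Dice overlap with the template ventricle prior ≥ 0.3; total
volume within [5 000, 250 000] mm³; at most 4 six-connected components of
≥ 50 voxels; non-empty posterior, right-frontal and right-temporal
compartments. A failing subject is reported with diagnosis `QC_FAIL` and
empty feature fields; it never aborts the batch.

### Classifier

A soft-margin linear SVM (C = 1 by default) on z-scored features, with
inverse-frequency class weights on by default because the clinical
cohorts this mimics are heavily imbalanced (tens of positives against
hundreds of negatives). The fitted decision function is extracted to a
plain `w·z(x) + b`, serialized as versioned human-readable text, so
prediction is exactly reproducible independent of the fitting backend. A
linear kernel is chosen for determinism and because the 6-feature regime
gives a kernel little to gain; it also keeps the anterior–posterior
weight interpretable. Scores ≥ 0 (ties included) map to
`bvFTD_compatible`.

### Evaluation

`classificationMetrics` reports sensitivity, specificity, accuracy,
false-negative/positive rates and both likelihood ratios
(LR+ = sens/(1−spec), LR− = (1−sens)/spec); LR+ with zero false positives
is reported as `Inf` with a flag rather than an error, so batch reports
never crash. The printed report rounds percentages to integers and ratios
to two decimals. Group comparisons use Welch two-sample t-tests (the
pooled-variance form is available via `varEqual = TRUE`) with Bonferroni
correction capped at 1. `misclassificationReport` contrasts true
positives against false negatives and false positives against true
negatives, per feature. Dice of two empty masks is defined as 1
(agreement on absence).

## The synthetic study conditions

All tests run on synthetic data because the clinical datasets this kind
of tool is validated on are access-restricted. The generator defines the
study conditions; its defaults are fixed and are not tuned per test:

* **Template.** 96³ voxels at 1 mm, world origin at the
  anterior-commissure-like anchor between the ventricles. The head is an
  ellipsoidal ICV (semi-axes 38 × 44 × 40 mm) with a white-matter core
  (intensity 70), a grey-matter shell (50) and CSF ventricles (10) on the
  [0, 100] scale. Each lateral ventricle is a body plus frontal, temporal
  and occipital horns, mirror-symmetric in x, with anterior/posterior
  volumes balanced at neutral factors (|apr_log| < 0.01). The atlas
  partitions the ICV by world-coordinate rules (frontal y > 10; parietal
  y ∈ [−40, 10], z > 10; temporal y ∈ [−40, 10], z ≤ 10; occipital
  y < −40; hemisphere by the sign of x).
* **Phantoms.** Shape factors act on compartment volumes (the spatial
  scale is the cube root): `aprFactor` on everything anterior to the
  −12 mm plane, `lrFrontalFactor`/`lrTemporalFactor` on the left frontal
  and temporal horns, `totalScale` globally. Corruption: additive
  Gaussian noise (default sd 3), a ±10% multiplicative linear bias field,
  a grey/white contrast multiplier emulating field-strength differences,
  and a random rigid+scale pose (±5 mm, ±0.05 rad, ±5% per axis). A
  rescan mode reuses a fixed pose with fresh noise and contrast, which
  leaves the ground-truth mask bit-identical — the basis of the
  repeatability harness.
* **Cohorts.** bvFTD-like subjects draw `aprFactor ~ N(1.30, 0.15)`,
  `totalScale ~ N(1.3, 0.15)`, age ~ N(63, 8); PPD-like subjects
  N(1.00, 0.15), N(1.0, 0.15), N(69, 10); an optional other-dementia
  group sits between (1.05, 1.15, age 74). The anterior–posterior
  contrast echoes the reported group statistics for misclassified versus
  correctly classified psychiatric subjects (≈1.26 vs 0.97), and the age
  separation echoes the reported older false negatives; these are
  configuration defaults chosen to exercise the method at realistic
  effect sizes, not claims of anatomical realism.
* **Fusion library.** Five template-space phantoms whose size and
  anterior–posterior factors are spread across the atrophy spectrum
  (totalScale 0.8–1.8, aprFactor 0.85–1.6, with mild jitter), as real
  expert-labelled libraries span the anatomy they must segment. Library
  images travel the same native→template interpolation path as pipeline
  targets so that patch statistics are commensurable — without this the
  contrast preselection systematically rejects valid matches against
  resampled targets.

What the phantoms deliberately do **not** model: gyral/sulcal anatomy,
partial-volume effects beyond trilinear smoothing, k-space artefacts,
non-affine anatomical variability, and third/fourth ventricles. Passing
tests therefore demonstrate that the pipeline's mathematics — geometry,
fusion, features, classification, reporting — is correct and stable under
noise, bias, contrast and pose perturbations; they do not certify
performance on clinical images.

## Numerical choices and degenerate inputs

* Problem sizes: tests and the acceptance script use 96³ phantoms, a
  5-entry library, 10-phantom segmentation cohorts and 200-per-group
  classifier cohorts — large enough for stable statistics at desk scale.
* Voxel indexing is 0-based with world coordinates at voxel centres;
  the template grid places centres at half-integer world coordinates, so
  no voxel sits exactly on the x = 0 or y = −12 planes.
* Constant images, single-class training data, empty posterior or
  right-hemisphere compartments, zero-variance correlations and empty
  metric denominators all raise typed errors naming the offending
  quantity; inside `runPipeline` any subject-level error is caught and
  recorded as `QC_FAIL`.
* Two-group comparisons of two exactly constant samples return p = 1
  (equal means) or p = 0 (different means) with a `degenerate_variance`
  flag instead of erroring.
* The published negative likelihood ratio for the bvFTD-vs-PPD task is
  0.31, while the unique integer confusion matrix consistent with the
  published cohort sizes and rates (tp = 10, fn = 4, fp = 4, tn = 32)
  yields 0.32; the package reports 0.32 and treats the difference as a
  rounding-path ambiguity in the published figure.

## Known limitations

Affine-only registration cannot normalize genuinely deformed anatomy;
the tool inherits this by design (its features are deformation-free on
purpose). The ICV estimate is only as good as the affine scale factor.
The reference classifier shipped by `makeFixtures` is trained on
synthetic cohorts: numerical parity with any clinically trained model is
out of scope, and the published model's kernel, C and coefficients are
not public. The automated QC is a surrogate for expert visual review and
its thresholds, while configurable, have not been validated against human
raters.
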