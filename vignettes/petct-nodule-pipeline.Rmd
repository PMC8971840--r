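---
title: "Automated PET-CT pulmonary-nodule classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated PET-CT pulmonary-nodule classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(petlung)
```

`petlung` implements a complete desk-scale chain for differentiating
malignant from benign pulmonary nodules on co-registered FDG PET-CT:
annotation-free localization of the lung fields, normalization of both
modalities, a 3D high-resolution multi-branch convolutional classifier with
a residual baseline, cross-validated evaluation with ROC/AUC statistics,
and a parametric synthetic thorax generator that makes every stage testable
without patient data. This vignette explains the model and procedures, the
parameters that matter, the numerical choices, and what the synthetic
experiments do and do not show.

## The problem

Incidental pulmonary nodules found on CT are benign or malignant, and the
distinction drives treatment. FDG PET adds a metabolic signal — malignant
nodules tend to accumulate more tracer — but fixed SUV cutoffs are
unreliable at the extremes. A classifier operating directly on the joint
PET-CT volume can in principle learn the joint morphologic-metabolic
signature. The practical obstacle is localization: either an expert marks
every nodule (slow, subjective), or the pipeline must find the relevant
anatomy by itself. The chain implemented here takes the second route: a
deterministic, rule-based procedure finds the lung fields from the images
alone, and the classifier sees a standardized sub-volume instead of an
expert's crop.

## Coordinate and unit conventions

Volumes are base-R arrays with dimensions `(row, col, slice)`, 1-based,
slice 1 the most superior; slices run superior to inferior. CT voxels are
Hounsfield units clipped to the 12-bit range [-1024, 3071]; PET voxels are
nonnegative raw activity (SUV calibration is irrelevant downstream because
model inputs are max-normalized). NIfTI is the supported on-disk format
(via RNifti, rescale slope/intercept applied on read); DICOM series
reading is out of scope — no R DICOM reader is part of the package's
dependency set, and the rescale arithmetic itself is exposed and tested as
`apply_rescale()`.

## Display windows and model-input normalization

A CT display window `(WL, WW)` maps HU linearly onto [0, 1] between
`WL - WW/2` and `WL + WW/2`, clipping outside; the ramp between the clip
points is the standard radiology convention. Two windows matter here:

* mediastinal, WL 40 / WW 400, clip bounds -160 / +240 HU — used by the
  localizer, because under it the tracheal lumen and lung parenchyma
  render black;
* lung, WL -400 / WW 1500 — used to normalize the CT channel of the
  classifier input.

The PET model input is divided by its volume maximum (per-volume rather
than per-slice, reading "the maximum of the image range" as the 3D input;
a per-slice flag exists). An all-zero volume is passed through with a
warning. The localizer's air threshold defaults to the mediastinal lower
bound, with voxels at exactly -160 HU counted as air; the choice of
`<=` over `<` moves single boundary voxels only and is immaterial on
phantoms.

## The automated lung localizer

Per trans-axial slice, viewed superior to inferior:

1. **Binarize**: air = HU at or below -160.
2. **Body contour**: the tissue (non-air) mask is hole-filled
   (`EBImage::fillHull`), so lungs and trachea do not split the body; its
   8-connected components are labeled (a compiled two-pass union-find) and
   the body is the largest region whose area is at least 10% of the image
   and whose centroid is at least 10% of the image side away from every
   border. The two quantifiers ("overly small", "biased toward the edge")
   are configurable; exact area ties go to the most central region.
3. **Central band**: starting at the image centre column and growing
   symmetrically, the narrowest column interval enclosing at least 33% of
   the body area. Only air inside the body and this band counts, which
   protects the ratio from hollow artifacts near the body margin on poor
   slices. An alternative reading (band's own area = 33% of body area) is
   available behind `band_interpretation = "band_area"`.
4. **Apex rule**: the first slice whose in-band air is at least 5% of the
   body area is the lung apex.
5. **Crop**: a 256 x 256 window centred on the apex slice's body centroid,
   over 96 consecutive slices from the apex down, gives the CT sub-volume;
   the PET sub-volume covers the same physical window at 64 x 64 (native
   crop when aligned with the PET grid, bilinear per-slice resampling
   otherwise). Volumes with fewer than 96 remaining slices are padded
   inferiorly with air (HU -1000 / activity 0) rather than rejected;
   windows that would leave the grid are shifted inward. Both events are
   recorded in the result's provenance, so a run is fully reconstructible.

The procedure is deterministic — identical inputs and parameters give
bit-identical crops — and in-plane translation-equivariant until border
clamping, both of which are asserted by tests.

## Manual-annotation preprocessing

The expert-annotation alternative crops 16 consecutive slices centred on
the representative slice (the slice of maximal nodule diameter): 8 above,
the slice itself, 7 below — the split is a convention the package fixes,
since only "adjacent" is inherent — with a 64 x 64 CT window centred on
the annotated point and the corresponding 16 x 16 PET window resized to
64 x 64 by bilinear interpolation. Nodules are interior structures, so
windows at volume ends shift inward instead of padding.

## The classifiers

No deep-learning framework is assumed: the package carries a compact 3D
convolution engine (im2col + BLAS matrix products, compiled scatter/gather
kernels, hand-written backpropagation verified against numerical
differentiation in the test suite, Adam with optional decoupled weight
decay, leaky rectifier activations with slope 0.05 so units cannot die
under small-batch training).

**High-resolution network.** The top branch runs at full input resolution
through every stage — no stride, no pooling — so fine structure is never
lost; stride-2 transitions spawn branches at 1/2, 1/4, ... resolution with
doubled channels; at the end of each stage every branch receives the sum
of all branches resampled to its resolution (strided convolutions
downward, 1x1x1 projection plus nearest upsampling upward). The head is a
1x1x1 convolution on the fused top branch, global average pooling, and a
linear layer to two classes. With this head the class-activation map is
exact: the malignant logit is the spatial mean of a fixed channel
combination of the last full-resolution feature map.

**Residual baseline.** A conventional counterpart: a stem followed by
stages that halve resolution and double channels with residual blocks in
between, then global pooling — the "continuously reduce the feature maps"
design the high-resolution model is contrasted with.

The two channels are lung-windowed CT and max-normalized PET, upsampled to
a common grid and concatenated (early fusion — the minimal reading of
"PET-CT input jointly"; a CT-only mode supports the modality-contrast
arms). Published descriptions of this architecture leave layer counts,
widths and the optimizer open; the package defaults (3 branches, base 8
channels, 2 blocks per stage, Adam 1e-3) are deliberately small and fully
configurable, and the experiments below state the sizes they use.

Training details: softmax cross-entropy, optional inverse-frequency class
weights for the 79/33 imbalance, seeded shuffling; `train_cv()` assigns
label-stratified folds by a seeded round-robin deal (fold sizes differ by
at most one overall and per class), trains one fresh model per fold and
scores only held-out cases.

## Evaluation statistics

AUC is the Mann-Whitney statistic with ties counted one half, computed via
midranks — exactly equal to all-pairs counting, which the tests assert.
Confidence intervals and the paired two-model comparison use the DeLong
structural-components estimator; the paired test accounts for the
covariance induced by shared cases. DeLong is the natural choice because
the common clinical ROC software implements it for correlated ROC curves.
Threshold metrics (sensitivity, specificity, accuracy) use score >=
threshold as the positive call, default 0.5, with a Youden-optimal option.
Cohort-table machinery: pooled-variance Student's t reconstructed from
printed group summaries (n, mean, SD) — the zero-variance corner returns
p = 1 for equal means and p = 0 otherwise, a documented convention —
Pearson chi-square without continuity correction, and the two-sided Fisher
exact test (delegated to `stats`; an enumeration oracle cross-checks it in
the tests).

## The synthetic thorax generator

Each phantom is an elliptical soft-tissue body (40 HU) in air (-1000 HU),
a tracheal air column above the apex, and two lung ellipses at -850 HU —
below the -160 HU threshold, as parenchyma renders black in the
mediastinal window — that appear at the apex slice at 60% linear scale and
ramp to full size inferiorly, with the medial lung edge held near the
midline so it stays inside the localizer's central band at every scale.
Nodules are spheres with configurable diameter, HU (default 20) and PET
uptake. PET is rendered at one quarter the in-plane resolution with
uniform background uptake 0.5 inside the body, per-slice Gaussian
smoothing (sigma 1 PET px), and a partial-volume floor that keeps
sub-resolution nodules visible as at least a one-pixel blob, as a scanner
PSF would. Gaussian HU noise (default sigma 10) is added to CT. An
optional cardiac/mediastinal blood-pool structure (`heart_uptake`) can
anchor the PET maximum; it is off by default and used by the
heatmap-localization experiment below. Everything is reproducible from a
single seed.

The truth object records both the geometric first lung slice and the slice
the 5% rule should select on clean geometry (computed by exact pixel
counting); the localizer is scored against the latter, so apex-recovery
tests measure noise robustness rather than the rule's own discreteness.

Cohorts default to 112 cases with the 79/33 malignant/benign split.
Malignant cases draw larger nodules (diameters N(30, 8) px at the 512
reference grid vs N(20, 6), scaled with the grid) and higher uptake
(N(6, 1) vs N(2, 0.8), truncated positive), which makes the learning task
separable by construction — a two-sample t-test on the generated uptakes
rejects easily at n = 112. The class-conditional distributions are
arguments, because which trait carries the signal matters for
interpretability experiments (below). A fast profile (44 x 64 x 64 grid
with crop 32 / 32 slices / PET crop 8) scales all geometry down by the
grid ratio; every rule is resolution-agnostic, so the fast profile
exercises identical code paths.

What the phantoms do **not** emulate: anatomical texture, respiratory
motion, attenuation or scatter artifacts, multi-nodule cases, and the
continuum of borderline lesions. Passing tests therefore demonstrate that
the machinery is correct and that the chain can recover constructed
signal; they say nothing about clinical discrimination performance, whose
published values depend on private patient data.

## Experiment sizes and numerical choices

The shipped tests run the full chain at sizes chosen for a single desktop
CPU core:

* localizer robustness: 100 randomized fast-profile phantoms (body size,
  apex, lung scale and noise sigma up to 20 HU all varied), apex within
  +/- 1 slice in at least 95%;
* cross-validated learning: the 112-case fast cohort, inputs pooled to
  (2, 8, 8, 8), both architectures at base 4 channels, 5 folds, 15
  epochs — both reach held-out AUC above 0.9 comfortably;
* overfit sanity: a 20-phantom cohort at the default class balance,
  (2, 16, 16, 16) inputs, two-branch configuration with weight decay —
  training accuracy reaches 1.0 in well under 30 epochs. Class balance
  matters here: strongly imbalanced towards informative draws, a balanced
  redraw can place a benign/malignant pair in the overlap tails of the
  uptake distributions whose PET footprints coincide under the fast
  grid's partial-volume floor, and such a pair resists memorization for
  over a hundred epochs even though a two-case fit separates it easily;
* heatmap localization: described below.

Integer-factor pooling/upsampling handles all resizing between crop and
model grids; bilinear interpolation is used only in-plane on PET crops.
Ties in `select_body_contour` go to the most central region; the band
growth stops as soon as the enclosed area reaches target, making the
interval the narrowest symmetric one up to single-column discreteness.

## Heatmap localization: design of the experiment

The class-activation map answers "which voxels drive the malignant
logit?". For that question to have a well-defined right answer on
phantoms, the class evidence must be spatially confined to the nodule —
otherwise a correct classifier is free to read the class off global cues,
and its activation map has no reason to peak at the lesion. The default
cohort violates this in a subtle way: with max normalization,
class-dependent uptake turns into a class-dependent *background* level (a
cue available everywhere inside the body), and any structure whose
brightness ratio to the rest differs by class is itself evidence. We
verified empirically that under such conditions the trained model
classifies perfectly while its activation peak sits on non-discriminative
bright structures.

The localization experiment therefore uses a cohort in which the evidence
is local by construction: zero PET background (every nonzero PET voxel
belongs to the nodule), uptake matched across classes, and class
separation by nodule diameter, with both class diameters resolvable at
the model grid — a mask smaller than one model voxel cannot anchor a
voxel-level localization oracle. The model is the full-resolution
single-branch configuration (the degenerate one-branch case of the
multi-branch network — its receptive field grows only through 3x3x3
convolutions, keeping features local), trained well past interpolation
with weight decay 1e-3; decay shrinks the head weights of
non-discriminative channels, which is the standard reason class-activation
maps concentrate on evidence-carrying features. Under this design the
maximum-heat voxel falls inside the nodule in essentially every case.

## Known limitations

* The compiled convolution engine is CPU-bound and sized for desk-scale
  experiments; it is not a substitute for GPU training at 256 x 256 x 96.
* PET-CT registration is assumed given (hardware-fused scanners); no
  software registration is performed.
* The localizer is rule-based by design and documented as such; it has no
  learned component.
* Only NIfTI I/O is provided; DICOM series must be converted upstream.
* Printed cohort statistics that do not reproduce from printed inputs
  under the named tests (a sex-row chi-square, a delayed-uptake t-test)
  are implemented by the standard formulas and the discrepancy is left
  documented rather than guessed around.
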