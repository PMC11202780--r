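---
title: "Methods: from radiotherapy DICOM to two-year survival classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from radiotherapy DICOM to two-year survival classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctsurv)
```

## The problem

Two-year overall survival of non-small-cell lung cancer patients can be
framed as a binary classification task on pre-treatment CT: did the patient
survive more than 730 days from the start of treatment? `ctsurv` implements
that pipeline end to end. The inputs are a per-patient axial CT series, a
radiotherapy structure set (RTSTRUCT) whose `GTV-1` ROI delineates the
primary gross tumor volume as per-slice mm contour polygons, and a clinical
table with survival time and censoring status. The outputs are (i) a
normalized 240 x 240 x 5 image stack centred on the tumor, (ii) the
`GTV1-SliceNum` clinical feature, and (iii) a trained 3-D convolutional
classifier whose loss directly penalizes confident false negatives and
false positives (PEN-BCE).

## Locating the tumor

RTSTRUCT contours do not store pixel masks; they reference CT slices by SOP
instance UID and carry vertices in patient coordinates (mm). The pipeline:

1. **UID intersection.** The slices carrying tumor are the intersection of
   the series' SOP instance UIDs with the UIDs referenced by the `GTV-1`
   contours (`gtv1_slice_uids()`), ordered by the z component of
   `ImagePositionPatient`. Slice order is geometric on purpose: filenames
   and `InstanceNumber` are unreliable in the wild, and both the
   coordinate transform and the slice stacking need z order. Ties (which
   should not occur in a well-formed series) break lexicographically by
   UID so the order is total and reproducible. Patients without a usable
   `GTV-1` ROI are excluded with a structured error; ROI matching is
   exact after whitespace stripping, with an opt-in regex mode because
   real structure sets show naming drift. Contours without an image
   reference are matched to the nearest slice by z and accepted within
   half a slice thickness -- a documented fallback, flagged by a warning.
2. **mm to pixel.** `mm_to_pixel()` applies the affine frame transform
   `x_px = (x_mm - x0) / xs` (and similarly for y) with the slice's
   `ImagePositionPatient` origin and `PixelSpacing`. The result stays
   fractional; rounding is deferred entirely to rasterization so no
   precision is lost before the fill.
3. **Rasterization.** `rasterize_contour()` fills the transformed polygon
   with the even-odd rule over pixel centres, including boundary pixels.
   Even-odd (rather than nonzero winding) makes self-intersecting
   hand-drawn contours rasterize deterministically. The fill is verified
   against an independent brute-force point-in-polygon oracle in the test
   suite; several contours on one slice (multi-region tumors) are unioned.

The package carries its own compact DICOM Part-10 codec (explicit and
implicit VR little endian, the CT and RTSTRUCT attributes this pipeline
uses). The writer backs the synthetic cohort generator; its output is
cross-validated against an independent DICOM implementation in the tests.
Compressed transfer syntaxes and DICOM networking are out of scope.

## Segmentation quality control

Three defect classes occur in public radiotherapy cohorts, and each gets a
distinct treatment (`run_qc()`):

* **Area collapse** (an almost-empty contour sandwiched between two full
  ones, an artifact of contour interpolation during delineation): an
  interior slice is flagged when its area falls below `tau` times the
  smaller neighbouring area, then repaired by shape-based interpolation --
  the signed Euclidean distance transforms of the two neighbours are
  averaged and thresholded at zero. `tau = 0.5` by default: natural
  cranio-caudal tapering is monotone toward the tumor ends and never
  triggers the rule, while a collapsed slice does. The threshold is
  configurable because no principled universal value exists.
* **Bilateral regions**: when a slice shows several connected components,
  only the dominant side is kept -- the side of the image midline with the
  larger tumor area summed over the whole stack; a tie goes to the side
  holding the largest single component, then left. The midline
  approximates the anatomical midline for centred axial scans.
* **Mislabeling** (the contour does not sit on the tumor): flagged only --
  when lung ROIs are available the tumor centroid is tested against their
  union -- and never auto-repaired, because the correct label cannot be
  established without a clinician.

QC is idempotent (a repaired stack passes a second run untouched) and never
changes the number of tumor slices, so `GTV1-SliceNum` is invariant under
repair. A limitation worth knowing: shape interpolation reconstructs an
intermediate shape, so repair accuracy depends on the tumor's slice extent.
For tumors spanning six or more slices the repaired mask overlaps the
ground truth at Dice 0.9+; for a three-slice tumor whose *peak* slice
collapsed, the peak geometry is simply gone and no interpolation can
recover it. The QC validation fixtures therefore use 6-10-slice tumors,
which is also where this artifact class arises in practice.

## Building the model input

The network sees a fixed-depth stack (default 5). `select_slices()` takes
the tumor-containing slice with the largest mask area plus its two
tumor-containing neighbours on each side; at the edges of the tumor range
the window shifts inward rather than oversampling, keeping real anatomy
whenever at least `depth` tumor slices exist. Ties in the area argmax break
toward the lower z index. With fewer than `depth` tumor slices,
`oversample_slices()` duplicates edge slices alternately -- an extra copy
of the last slice first, then of the first -- which preserves spatial order
and keeps the peak slice central; a single-slice tumor becomes five copies
of itself. The 4-slice ablation variant drops the last slice of the 5-slice
window (a documented, configurable choice).

Intensities are normalized twice, mirroring the two-stage byte/unit
convention: `dicom_to_byte_image()` maps stored values to integers in
[0, 255] via `round((x - min) / (max - min) * 255)`, then stacks are scaled
to [0, 1]. The byte formula's historical rendering divides by `max` alone,
which overshoots whenever `min != 0` (CT values are negative after
rescale); the range denominator is the default because it actually
delivers the stated 0-255 range, and a `strict` flag keeps the literal
variant for comparison. A constant slice maps to zeros with a warning
rather than dividing by zero. Resizing (to 240 x 240, bilinear,
anti-aliased) happens on the byte image; the ROI variant instead crops
128 x 128 pixels centred on the midpoint of the tumor's minimum bounding
rectangle, clamped into the image and zero-padded only when the image is
smaller than the crop.

## The GTV1-SliceNum feature

With a fixed slice thickness (3.0 mm in the reference cohort), the number
of distinct CT slices carrying a `GTV-1` contour is a direct proxy for the
tumor's cranio-caudal extent -- the imaging analogue of tumor thickness,
a known prognostic factor. `gtv1_slice_num()` counts distinct slices (a
slice with two tumor regions counts once) and `feature_importance()` ranks
it against the standard clinical covariates with impurity-based importances
from a CART tree (`rpart`) or a random forest (`randomForest`), normalized
to sum to one. Ordinal covariates are median-imputed and categoricals
mode-imputed with a fixed, sorted level order, so the encoding -- and the
fit, given a seed -- is reproducible.

Labels follow the strict 730-day rule: `label = survival_time > 730`, so a
patient who died at exactly 730 days counts as a short survivor. Under the
`include_censored` policy a censored patient with follow-up beyond 730 days
is a known long survivor; a censored patient with shorter follow-up has an
epistemically unknown class and is labelled 0, flagged in a
`label_uncertain` column. That choice is forced by cohort accounting (no
censored patient is dropped under the inclusive policy), not by knowledge
of the outcome, and the flag makes the uncertainty explicit downstream.

## The loss family and PEN-BCE

All losses are batch means with natural logarithms over probabilities
clipped to `[1e-7, 1 - 1e-7]`. Besides BCE, the package provides the
weighted BCE, the focal loss, the asymmetric loss (asymmetric focusing
plus probability shifting), and the real-world-weighted cross-entropy.
The proposed PEN-BCE adds hinge-squared penalties to BCE:

$$\mathrm{PEN\text{-}BCE} = \frac{1}{N}\sum_{i=1}^{N}\Big\{
-\big[y_i\ln p_i + (1-y_i)\ln(1-p_i)\big]
+ \alpha\, y_i \max(0,\, p_{FN}-p_i)^2
+ \beta\,(1-y_i)\max(0,\, p_i-p_{FP})^2\Big\}$$

A positive predicted below `p_FN` pays an extra quadratic penalty scaled
by `alpha`; a negative predicted above `p_FP` pays one scaled by `beta`.
For a single positive this reduces to `-ln p + alpha * max(0, p_FN - p)^2`,
which pins down the sign convention (the penalty adds on top of the
negated log-likelihood). Two smaller conventions are worth recording: the
penalty terms share the `1/N` batch mean with the BCE part, which is what
makes the loss an exact size-weighted mean over concatenated batches; and
the focal loss is implemented in the standard two-sided `p_t` convention
(`p_t = p` for positives, `1 - p` for negatives), since the one-line
rendering with a leading `y_i` factor would silently delete all negative
samples -- a `strict` flag retains that literal form. Every loss ships with
its analytic gradient (subgradient 0 exactly at the hinge), verified
against central finite differences, so evaluation and training share one
set of numerics. Default PEN-BCE parameters are `alpha = 1, beta = 5,
p_FN = 0.5, p_FP = 0.2` -- the best row of the ablation grid
(`pen_bce_param_grid()`).

Why does `beta >> alpha` reduce false positives? Above `p_FP` every
negative feels a restoring gradient of `2 beta (p - p_FP)` on top of the
BCE term, so confident scores on negatives become expensive while the
positive side is nearly untouched. `pen_bce_fp_study()` demonstrates this
on a two-feature logistic task with a roughly 1:3 class ratio: across
seeds, PEN-BCE training cuts test-set false positives at the 0.5 threshold
to a fraction of the BCE count, at the cost of extra false negatives --
the intended asymmetric trade.

## The classifier and training recipe

`build_model("resnet34_3d")` is a 3-D residual network with basic-block
stages (3, 4, 6, 3) at 64/128/256/512 channels, a (7, 7, 3) stem, global
average pooling and a single sigmoid unit. Two depth-specific adaptations:
the slice axis is never strided (a 5-slice input leaves no room for depth
downsampling; the global pool collapses it), and the blocks omit batch
normalization -- at the CPU batch sizes and desk-scale problems this
package targets, plain He-initialized blocks train stably, and omitting
the extra state keeps the from-scratch engine small. `"tiny3d"` is a
two-convolution sibling used for fast experiments and tests; both share
one forward/backward engine (compiled 3-D convolution and pooling with
exact gradients).

Training follows the reference recipe: SGD with Nesterov momentum 0.9,
initial learning rate 2e-5, weight decay 1e-6, batch size 16, up to 200
epochs, learning rate times 0.9 after a 25-epoch validation-loss plateau,
early stopping with best-weight restore, all inside 5-fold stratified
cross-validation over the training portion of an 85/15 stratified split.
Two under-specified corners are resolved as follows: "validation loss
remained constant" is read as no improvement beyond 1e-4 for the patience
window, and early stopping uses a 50-epoch patience. Test metrics
(accuracy at 0.5; rank-based AUC with midranks, so ties and the
brute-force pairwise definition agree exactly) are reported per fold model
on the held-out 15% and averaged. A single-class test set yields `NA` AUC,
never a fabricated 0. Everything -- splits, initialization, shuffling,
augmentation -- is driven by one seed, and a PEN-BCE run with
`alpha = beta = 0` reproduces the BCE run bit for bit, which the tests
assert.

Augmentation (the ablation's rotate + shift) appends one randomly rotated
(up to 15 degrees) and shifted (up to 10% of each in-plane dimension) copy
of every training sample; ranges are package defaults since only the
transform family is prescribed. `run_ablation()` drives the whole grid --
slice depth, augmentation, censoring policy, input variant, and the
PEN-BCE parameter grid -- holding seeds and initial weights fixed across
cells except for the varied axis.

## What the synthetic cohorts emulate (and what they do not)

`make_cohort()` emits a fully self-contained cohort: per-patient DICOM CT
series (axial, 3.0 mm spacing, 0.977 mm pixels, signed 16-bit with
rescale -1024), an RTSTRUCT with lungs / spinal cord / GTV ROIs whose
contours are 32-vertex polygonizations of ellipsoid cross-sections, a
clinical CSV with the reference column names, and a ground-truth manifest.
Tumor geometry is exact by construction: an ellipsoid with half-extent
`1.5 k` mm centred appropriately intersects exactly `k` slices, so the
manifest slice count is analytic, and 32-gon polygonization keeps
cross-section areas within 5% of the analytic ellipse for regions of 100+
pixels. Survival is Weibull (shape 1.3) with log-scale
`7.0 - 0.12 * slice_count`, giving roughly a one-third long-survivor rate
and a strong negative extent-survival association; censoring is Bernoulli
at 11.4% with a uniform fractional follow-up time for censored patients --
drawing the censoring indicator directly (rather than racing survival
against an independent follow-up clock) is what makes the realized
censored fraction match the nominal rate without calibration. Error
injection (`inject_area_jump()`, bilateral second tumors, displaced
contours) records every corruption plus the pre-corruption contours in the
manifest, which is what the QC tests score against. Fixtures default to
128 x 128 images and 12-20 slices per patient so suites stay fast; the
mm-to-pixel geometry is exercised identically at any raster size, and the
full-scale dimensions (512 x 512, 75-297 slices) are a parameter away.

What passing on these fixtures does **not** show: real CT texture (the
phantoms are piecewise-constant HU plus Gaussian noise), scanner private
tags and encoding quirks, genuinely ambiguous tumor boundaries, or
classifier performance on real cohorts -- the training harness is
validated on a separable synthetic task (bright-blob detection at
32 x 32 x 5, n = 80, 20 epochs, 5-fold), which checks the machinery, not
clinical signal. Reproducing the reference cohort's headline metrics
requires the real data and GPU-scale training and is explicitly out of
scope here; the desk-scale problem sizes above (200 rasterization
polygons, 50 QC patients, 100 importance seeds, 10 behavioral-study seeds)
are the package's chosen validation conditions.

## Numerical choices, in one place

* Probability clipping `1e-7` before any log; natural logs throughout.
* Even-odd fill over pixel centres, boundary included; 0-based pixel
  frame in the transform, 1-based indices in R containers.
* Byte normalization by range (`max - min`), `strict` flag for the
  max-only variant; constant images map to zeros with a warning.
* Signed-distance interpolation threshold at `> 0`; an empty neighbour is
  copied, two empty neighbours are an error.
* Area-jump `tau = 0.5`; argmax ties toward lower z; laterality ties to
  the largest single component, then left.
* Plateau min-delta `1e-4`, patience 25, factor 0.9; early-stop patience
  50 with best-weight restore.
* He-normal initialization; Nesterov update
  `v' = m v - lr g; w' = w + m v' - lr g`.
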