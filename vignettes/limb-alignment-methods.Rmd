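---
title: "Automated lower limb alignment measurement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated lower limb alignment measurement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

On a weight-bearing antero-posterior full-leg radiograph, lower limb
alignment is quantified by five angles built from two mechanical axes and
three joint lines:

* **mFAmTA** (hip-knee-ankle angle): angle between the mechanical femur
  axis (femoral head centre to knee centre) and the mechanical tibia axis
  (knee centre to ankle centre). In this package's convention a neutral leg
  measures 180&deg;, varus less than 180&deg;.
* **FSAmTA**: the same construction with the anatomical femoral shaft axis
  (the diaphyseal midline) in place of the mechanical femur axis.
* **mMPTA**: medial angle between the tibial mechanical axis and the
  tibial plateau joint line.
* **mLDFA**: lateral angle between the femoral mechanical axis and the
  femoral condylar joint line.
* **mLDTA**: lateral angle between the tibial mechanical axis and the
  ankle joint line (taken from the two talar-dome landmarks; the talus
  model places only two points, which forces this reading of the ankle
  line even though the tibial plafond is the classical reference).

`limbalign` implements the fully automatic multi-stage workflow for these
measurements: window-based preprocessing, instance segmentation of femur,
tibia, fibula, talus and knee-implant components, per-leg grouping and the
fibula/tibia leg-side rule, four region crops (proximal femur, knee
-- native or TKA -- and talus) canonicalized to right-leg orientation at
256 x 256, heatmap-regression landmark placement, back-projection, and
angle computation with per-parameter availability accounting. A companion
statistics module provides the agreement battery used to validate such
pipelines (mean error with 95% CI, SD, RMSE, Pearson r, absolute-agreement
single-measure ICC with an F-based CI).

## The synthetic phantom

No clinical images ship with the package. Instead, `generate_phantom()`
renders schematic AP legs from capsule/disc/polygon primitives (background
intensity 0.1, bone 0.6, implant 0.95, Gaussian blur, seeded additive
noise) and returns exact ground truth: all landmark positions, all
structure masks, the anatomical shaft axis, and the five generating angles
in closed form,

```
mFAmTA = 180 - varus,  FSAmTA = 180 - varus - femoral_anatomical_angle,
mMPTA  = 90 - plateau_obliquity,  mLDFA = 90 + condylar_obliquity,
mLDTA  = 90 + ankle_obliquity.
```

The geometry is constructed so that the oracle path (ground-truth
segmentations and landmarks driven through the cropping, back-projection
and goniometry stages) reproduces these closed forms to machine precision;
that identity is the package's master correctness property.

Two renderer choices matter for what the phantom can and cannot test:

* **Observability.** Every landmark that carries angular information lies
  on visible anatomy: the talar dome's flat superior edge runs along the
  ankle joint line and its two landmarks sit exactly on the dome's edge
  corners; plateau, condylar and implant edge landmarks sit on their
  rendered edges. During development an earlier variant clipped the dome
  perpendicular to the tibial axis, which made the ankle obliquity
  literally invisible in the talus crop -- no detector can recover what the
  image does not contain, and the rendered geometry was corrected.
* **Default ranges.** `sample_phantom_specs()` draws varus/valgus within
  &plusmn;8&deg;, joint-line obliquities within &plusmn;4&deg;, the
  anatomical-mechanical femoral angle in 5-7&deg; and segment lengths
  within about &plusmn;8% -- a plausible arthroplasty-referral spread.
  These are plausibility choices, not a fitted morphometric model; the
  phantom has no osteophytes, soft tissue, exposure gradients or stitching
  artefacts, so passing tests demonstrate the correctness of the pipeline
  logic and the learnability of stereotyped anatomy, not clinical-grade
  performance.

## The trainable stages

The package runs on CPU inside R, so both learned stages use a fixed
multi-scale convolutional encoder (Gaussian pyramid, gradient and
structure-tensor channels, normalized coordinates) with a small trained
head; one "epoch" is one shuffled pass over the training items with a
momentum-SGD update per item, and every model records its per-epoch loss.

* **Segmentation** is a per-pixel multinomial logistic head over
  flip-symmetric features at half resolution, followed by
  connected-component instancing, score thresholding (default 0.5),
  per-label mask-IoU suppression (0.5) and at most two instances per label
  for bilateral images. A second same-label instance must be horizontally
  distant (a genuine contralateral leg); nearby fragments are suppressed.
  The two implant components are pooled at the argmax and split by their
  proximal/distal order, which is far more reliable than a per-pixel
  decision between two classes that differ only by a small vertical
  offset. Exactly half of the training images (rounded down) are flipped
  horizontally so the model is side-insensitive; because the features are
  also flip-symmetric by construction, segmenting a mirrored image and
  mirroring back reproduces the original masks.
* **Landmark placement** is heatmap regression: a trained linear (1 x 1
  convolution) decoding layer produces one 128 x 128 heatmap per landmark
  (Gaussian targets, sigma 4 px at crop scale); training augments crops by
  rotation within &plusmn;10&deg; and scaling within 0.9-1.1 with
  coordinates co-transformed. Decoding takes the channel argmax refined by
  a 3 x 3 centre of mass, with confidence = channel peak over the global
  maximum; peaks below the threshold (default 0.2) are flagged missing and
  poison exactly the parameters that consume their roles.

A linear decoder over fixed features localizes coarsely (roughly 10 px at
crop scale on the phantom), so detection adds refinement stages that are
learned from the same training crops and are the package's own design:

1. a per-landmark Gaussian positional prior (training mean and spread)
   multiplies the heatmaps before decoding, suppressing confusions between
   similar-looking landmarks such as the mirrored contralateral corner;
2. a robust affine fit of the training mean configuration replaces
   outlying or missing detections with their shape-predicted positions
   (the affine absorbs the anisotropic crop scaling);
3. per-landmark appearance templates are aligned by normalized
   cross-correlation search plus two-scale Lucas-Kanade translation;
   landmarks whose template alignment slides along a self-similar edge
   (measured on the training crops themselves) keep their shape positions
   instead;
4. role-aware steps at original-pixel pitch (the crop resampled through
   its recorded transform, where structure size is constant): the femoral
   head is found as a whole disc and the five head-contour points are laid
   on the fitted circle -- the downstream Kasa circle fit consumes only
   the centre, which a disc alignment estimates far more robustly than
   five independent edge points; the condylar, plateau and implant-tray
   endpoint pairs are snapped perpendicular onto an edge refit from short
   one-sided intensity profiles at interior stations (one-sided, because a
   symmetric window would straddle the parallel opposing joint edge whose
   distance varies with the independent obliquities); a learned pair-offset
   guard re-anchors a grossly inconsistent talus corner on its partner.

Contrast enhancement of the crops is deterministic contrast-limited
(clipped-histogram) equalization. Plain rank equalization is unsuitable
here: on a nearly two-level crop it spreads the intra-structure noise
across the full intensity range by construction (the output marginal is
uniform), destroying the signal-to-noise ratio that sub-pixel placement
needs. The clip limit (4 x the uniform bin count) bounds the slope of the
intensity map while preserving the enhancement.

Landmark models are trained on oracle crops whose boxes receive Gaussian
jitter (SD 2 px per edge) emulating segmenter box noise, so the crop-frame
variability at inference is represented in training.

## Geometry and availability

`build_axes()` consumes landmarks by *role*, never by name: head centre =
circle fit of the head-contour points; femoral knee centre = condylar
notch (native) or midpoint of the femoral-component tangents (TKA); tibial
knee centre = midpoint of the tibial spines (native) or tray edges (TKA);
ankle centre = talus midpoint; joint lines through the role-tagged
medial/lateral pairs. The anatomical shaft axis comes from the femur mask
(least-squares line through per-row centroids over the 40-70% span of the
bounding box) -- the one consumer of masks in the angle stage -- except on
the oracle path, where the analytic axis is used: a rasterized mask cannot
support the 10^-6-degree recovery property (its quantization error is of
order 0.01-0.1 degree, and mask-based FSAmTA is tested separately at a
rasterization-honest 0.2 degree).

Signed angles use an atan2 cross/dot construction with a side-dependent
sign so that varus is positive for both legs; medial/lateral rays come
from the role-tagged landmark pairs, which stay side-correct because crops
are canonicalized before placement. All five angles are invariant to
rigid motion, uniform scaling and mirroring-with-side-toggle of the
inputs.

Any missing structure or low-confidence landmark marks the dependent
quantities unavailable with a machine-readable reason: without a talus
there is no ankle centre, hence no tibial mechanical axis, and only mLDFA
survives; without proximal-femur landmarks there is no head centre, mLDFA
and mFAmTA drop out, but FSAmTA is still computed from the mask shaft
axis. `detection_rates()` turns a batch of reports into the per-parameter
availability table.

## Reliability statistics

`icc_a1()` implements the two-way, absolute-agreement, single-measure
intraclass correlation from the ANOVA mean squares,

```
ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)),
```

with the McGraw-Wong F-distribution confidence interval; the two-way
absolute-agreement form is the standard reading for a fixed pair of
raters, and the F-based interval was chosen for closed-form testability.
`agreement_stats()` reports mean difference with a t-interval, sample SD
(n-1) and RMSE; the identity `RMSE^2 = ME^2 + SD^2 (n-1)/n` holds exactly
and is what lets printed mean-error and SD cells of published reliability
tables reconstruct their printed RMSE (`check_printed_rmse_identity()`;
the four bundled rows were selected to be insensitive to table rounding at
printed precision). Reports are pairwise-complete per parameter, so n may
differ between parameters. Pearson's r and its two-sided p (null of zero
correlation) come from the standard product-moment formula.

## Numerical choices and problem sizes

* Coordinates are 0-based with origin top-left, x rightward, y downward;
  boxes are half-open; the crop transform is corner-aligned
  (`x_image = offset + unflip(scale * x_crop)`) and round-trips points to
  1e-9 px.
* Standard radiographic display (patient's right on the viewer's left) is
  assumed and is an overridable flag of the side rule; mirrored displays
  invert the fibula/tibia decision.
* Degenerate inputs are explicit errors (collinear circle fits, too-thin
  shaft masks, empty ranges, zero-width windows) or availability signals
  (missing structures), never silent NA propagation.
* The packaged study sizes keep every stage CPU-friendly: the segmenter
  trains on 30 phantoms (30 epochs), each landmark model on 40 crops with
  one augmented copy each (30 epochs); held-out evaluations use 10 crops
  (landmarks, IoU) and 30 phantoms (end-to-end). On the phantom these
  sizes give held-out bone IoU of roughly 0.65-0.75, mean talus landmark
  error of about 2-3.5 px at crop scale depending on the evaluation draw,
  and a pooled five-parameter end-to-end angle RMSE of about 1.6-2.0
  degrees -- the same order as published human-vs-AI agreement for this
  task; the pooled RMSE is the metric the acceptance checks use.

## Known limitations

* The phantom is schematic: no pathology, no exposure variation, no
  stitching seams, no hip implants, and implant models cover only
  bi-component TKA. Results on it bound pipeline correctness, not
  clinical accuracy.
* The per-pixel segmentation head relies on the phantom's stereotyped
  vertical layout (normalized row features); it is a stand-in
  architecture for the stage contract, not a general-purpose bone
  segmenter.
* Landmarks whose position has no local image evidence (e.g. outline
  points inside homogeneous regions) are carried by the shape model and
  inherit its accuracy.
* mFAmTA is reported as an angle near 180 degrees; users preferring the
  deviation form can take `180 - mFAmTA`.
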