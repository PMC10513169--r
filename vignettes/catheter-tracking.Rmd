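---
title: "Image-based tracking of gadolinium-filled balloon catheters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based tracking of gadolinium-filled balloon catheters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During MRI-guided cardiac catheterization the tip of a balloon wedge
catheter — its balloon filled with dilute gadolinium so it appears as a
compact hyper-intense blob — must be followed in real time so the imaging
plane can be repositioned as the catheter moves. Manual plane tracking
prolongs procedures; automatic image-based tip detection removes that
burden. `cathtrack` implements an automatic, parameter-free detection
pipeline for this setting: a segmentation network finds candidate balloon
signal in each of three contiguous slices acquired per time point (one
*dynamic*), and a deterministic post-processing step reduces the candidates
to at most one tip estimate per dynamic.

The pipeline has four parts, each a module of this package:

1. **Semi-artificial training data** (`generate_phantom()`,
   `simulate_catheter()`, `build_dataset()`): backgrounds with a
   synthetically inserted balloon signal and programmatically exact
   ground-truth masks.
2. **Segmentation** (`build_model()`, `train()`, `predict_mask()`): a
   compact residual encoder-decoder trained with the Dice loss.
3. **Tracking** (`extract_regions()`, `select_candidate()`,
   `track_sequence()`): connected-component analysis and
   highest-intensity disambiguation across the three slices.
4. **Evaluation** (`classify_detection()`, `compute_metrics()`,
   `aggregate_patients()`): a center-of-mass detection criterion with
   per-patient metrics and cross-patient aggregation.

## The balloon signal model

The balloon is modelled as a 2D anisotropic Gaussian added to the
underlying image. With per-axis standard deviations $\sigma_x, \sigma_y$
(each drawn from $\{1.5, 2.5\}$ px), an integer rotation
$\theta \in [0^\circ, 359^\circ]$ and an amplitude factor
$a \in \{2, 3, 4\}$ (200–400% in steps of 100%), the composite image is

$$I'(p) = I(p) + a \, I(c) \, \exp\!\left(-\tfrac{1}{2} d^2(p)\right),$$

where $c$ is the chosen center pixel and $d(p)$ is the Mahalanobis
distance of pixel $p$ from $c$ under the rotated covariance
$R_\theta \,\mathrm{diag}(\sigma_x^2, \sigma_y^2)\, R_\theta^\top$. Scaling
the peak to the *local* intensity $I(c)$ makes the balloon's conspicuity
consistent across dark and bright placements, as it is in T1-weighted
imaging with partial-saturation contrast. Two modelling choices were
genuinely open:

* **Composition rule.** The amplitude convention ("percent of the
  underlying signal") fixes the peak increment but not whether the signal
  replaces or adds to the background. We add it: additive composition
  preserves background texture under the balloon, which matches the
  partial-saturation appearance and keeps the model linear in $a$
  (`simulate_catheter()` minus the input recovers $a I(c) G$ to machine
  precision, a tested invariant).
* **Mask rule.** "Within 1.5 standard deviations" of an anisotropic
  rotated Gaussian is read as Mahalanobis distance $\le 1.5$, i.e. the
  rotated ellipse with semi-axes $1.5\sigma_x, 1.5\sigma_y$. The
  implementation is verified against a brute-force per-pixel covariance
  scan over the full $\sigma \times \theta$ grid; the isotropic
  $\sigma = 1.5$ ellipse contains exactly 21 pixels.

Coordinates are R's native 1-based (row, col) throughout; rotation is
counter-clockwise about the center in image space. No acceptance-relevant
quantity depends on the origin convention.

## Phantom backgrounds: what they emulate and what they do not

Real cine-MR backgrounds are not distributable with the package, so
`generate_phantom()` produces a procedural stand-in with the three
features that matter for this task: a low-intensity noisy tissue
background, mid-intensity blood-pool structures (elliptical chambers and a
curved tubular vessel — the regions where a catheter plausibly travels,
and where placements are sampled with a border margin of at least
$3\max\sigma$ px), and a hyper-intense fat-like band hugging one border.
The band is deliberately in the same intensity range as a dim balloon: it
is the confounder on which false-positive suppression is exercised.

The phantom does **not** model MR physics — no bSSFP banding, coil
sensitivity profiles, undersampling or partial-Fourier artifacts, and no
anatomical variability beyond randomized ellipse/vessel geometry. Passing
the package's end-to-end tests therefore demonstrates that the method and
its implementation work as specified on data matching the signal model; it
does not certify clinical performance on patient images, which must be
assessed with user-supplied data (the loaders in `read_dataset()` accept
any real grayscale frames written in NIfTI with a manifest).

## Dataset conditions

The default `dataset_config()` mirrors the reference study design at desk
scale: 8 training and 4 validation subjects (disjoint backgrounds — the
split is by subject, never by frame), one balloon per frame, and exactly
10% catheter-free training frames with all-zero masks so the network
learns to output nothing when nothing is there. Every frame carries its
**own** background slice, emulating the multi-slice stack a subject
contributes in practice; this per-frame background diversity (hundreds of
distinct fat-band and blood-pool geometries rather than a dozen) is what
makes the learned false-positive rejection generalize to unseen
backgrounds. We use 40 frames per
subject at 64 × 64 px (320 training frames), a size chosen so that a full
study — data generation, 40 epochs of training, and evaluation on 60
held-out dynamics — completes in a few minutes on one CPU core while
leaving the class imbalance extreme (the balloon covers ~0.5% of a
frame). Everything is bit-reproducible from the configuration seed; a
single master seed fans out to per-stage seeds by fixed offsets
(`derive_seed()`).

## The segmentation network

The network is a compact residual encoder-decoder written directly in this
package (R for the graph, C++/BLAS for the convolutions): a three-stage
encoder (8/16/32 channels, two 2× max-pool downsamplings) whose deeper
stages carry identity-skip residual blocks, nearest-neighbour upsampling
decoder stages with U-Net-style skip concatenations, a 1 × 1 fusion at
full resolution, and a single-channel sigmoid head. It has ~25k
parameters — deliberately small: the balloon is a compact, high-contrast
blob, and the hard part of the task is rejecting bright confounders, not
representing complex shapes. Design notes:

* **Input normalization.** Each grayscale frame is rescaled to $[0, 1]$
  by its own min/max, replicated to three channels, then standardized by
  the stored per-channel constants of `imagenet_stats()` (overridable).
  A constant image maps to all-zeros with a warning.
* **Padding.** Inputs are reflect-padded to a multiple of the encoder
  downsampling factor (4) and cropped back after decoding, so arbitrary
  frame sizes work at inference.
* **Loss.** Soft Dice loss with smoothing $\varepsilon = 1$ in numerator
  and denominator: $1 - (2\sum pt + \varepsilon)/(\sum p + \sum t +
  \varepsilon)$. The smoothing keeps the loss defined — and exactly zero
  for a perfect prediction — on the 10% of frames whose target is empty.
* **Optimization.** ADAM with the conventional $\beta_1 = 0.9$,
  $\beta_2 = 0.999$. The full-scale reference recipe in
  `training_config()` uses learning rate $10^{-5}$, batch 64, 200 epochs;
  the scaled study (`run_demo_study()`) uses the standard ADAM default
  $10^{-3}$ with batch 32 and 40 epochs, appropriate for its ~300-frame
  dataset trained from random initialization. Per-epoch mean training and
  validation Dice losses are recorded; the delivered weights are those of
  the epoch with the **lowest validation loss** (first epoch on ties),
  kept as a running best so only one snapshot is stored.
* **Threshold.** A sigmoid activation $\ge 0.5$ (inclusive) is classed as
  balloon. The threshold is fixed, part of the method's parameter-free
  claim.
* **Correctness.** The hand-derived backward pass is verified against
  central finite differences through every layer in the test suite
  (relative error $\sim 10^{-6}$), and the batched Dice gradient against
  a finite-difference probe.

Training is deterministic given the configuration seed up to BLAS
summation order; tests that depend on training therefore assert with
margins, never bitwise.

## Multi-slice disambiguation

Per dynamic, the three predicted masks are split into 8-connected
components (diagonal contacts merge — balloon blobs are compact, and
diagonal splits are thresholding artifacts; 4-connectivity is available).
Every region is scored by the **mean** underlying-image intensity over its
pixels — mean rather than peak or sum so the score is robust to region
size; peak scoring is selectable. The single highest-scoring region across
all three slices becomes the tip estimate, its unweighted centroid the tip
coordinate. When the balloon straddles two adjacent slices this rule picks
the slice containing most of the balloon, which is exactly the information
a prospective slice-tracking controller needs. Ties resolve
deterministically (lowest slice, then largest region, then smallest
(row, col) centroid), so inference is entirely seed-free. No state is
carried between dynamics, and no motion model or trajectory prior is used.

## Evaluation scheme

A detection is a **true positive** only when exactly one predicted region
exists and its center of mass — the real-valued centroid rounded to the
nearest pixel — lies on a foreground pixel of the ground truth. No
prediction with no catheter is a **true negative**; a catheter with no
prediction at all is a **false negative**; everything else (wrong
region(s), multiple regions, or a detection on an empty ground truth) is a
**false positive**. The FP-vs-FN boundary when the catheter is present but
only wrong regions are predicted is genuinely ambiguous; we count it FP by
default, with `fn_if_missed = TRUE` as the alternative convention.

Two granularities are provided: `evaluate_frames()` scores the network
alone, one frame at a time against each frame's own ground truth, and
`evaluate_dynamics()` scores the complete pipeline per dynamic.
For per-dynamic evaluation, the three per-slice ground-truth masks are
collapsed by keeping only the region with the highest mean intensity
(`make_multislice_gt()` — the same scoring as the tracking step). Accuracy,
sensitivity and specificity are computed per patient and aggregated as
unweighted cross-patient means; the spread is the population standard
deviation (divisor $n$), which reproduces the reference sensitivity and
specificity spreads from `reference_patient_metrics` at one decimal (the
accuracy spread is sensitive to rounding of the per-patient inputs and is
reported as computed). Metrics with zero denominators propagate as `NA`
with a warning rather than 0 or 100, and are excluded from aggregation.
Operator agreement between two manual segmentations uses the mutual
center-of-mass criterion (`operator_agreement()`), symmetric by
construction.

## The scaled reference study

`run_demo_study()` ties the stages together under fixed conditions: the
default dataset (320 training / 160 validation frames), 40 epochs of
training from random initialization, and 60 held-out dynamics from 4
unseen phantom subjects, 30% of them catheter-free so per-patient
specificity is measurable, and 30% of the positive dynamics showing the
balloon in two adjacent slices (at half amplitude) to exercise the
disambiguation step. Within a dynamic the three slices share the
subject's anatomy but carry independent acquisition noise, as three
separately acquired planes would. The test suite runs this study for three independent
seeds and requires seed-averaged per-dynamic sensitivity and specificity
of at least 90%, and a mean tip-localization error on correctly detected
dynamics below $1.5 \max\sigma = 3.75$ px. `scripts/acceptance.R` runs the
same study once for a user-supplied seed and writes every headline
quantity to JSON.

## Degenerate inputs and numerical conventions

* Constant images: range normalization maps them to zeros, with a warning.
* Zero-intensity center pixel: balloon placement is rejected (the
  amplitude would be undefined).
* Empty masks: region extraction returns zero rows; a dynamic with no
  regions yields `present = FALSE` rather than a coordinate.
* Centroid rounding is half-away-from-zero, independent of R's banker's
  rounding.
* Seeds derived from the master seed always fit in a signed 32-bit
  integer.

## Known limitations

* The phantom generator is a stand-in for real cine-MR backgrounds; see
  above for what that does and does not demonstrate.
* The network is a compact design, not a 34-layer encoder; at the
  package's frame sizes and signal model this capacity is sufficient (the
  end-to-end tests hold with margin), but users targeting full-resolution
  clinical frames should expect to retrain and may need a larger
  `base_channels`.
* Only positive-contrast (gadolinium-filled) balloons are modelled;
  negative-contrast (gas-filled) balloons would need retraining with an
  inverted signal model.
* Training reproducibility is exact only up to BLAS summation order.
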