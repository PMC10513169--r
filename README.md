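# cathtrack

Automatic, parameter-free, image-based tracking of gadolinium-filled
balloon-catheter tips in dynamically acquired multi-slice MR images.

During MRI-guided cardiac catheterization, the tip of a balloon wedge
catheter (its balloon filled with dilute gadolinium) appears as a compact
hyper-intense blob in real-time MR images. Keeping the imaging plane on
that tip currently requires frequent manual repositioning. `cathtrack`
implements the full post-processing pipeline that automates this: for each
*dynamic* (one time point = three contiguous slices) it segments candidate
balloon signal in every slice with a neural network, reduces all candidates
to at most one tip estimate, and evaluates detection performance with a
center-of-mass criterion. It is aimed at interventional-MRI researchers who
want a reproducible, end-to-end reference implementation they can retrain
on their own data.

## The method

**Training data.** Real annotated catheter images are scarce, so the
network is trained on *semi-artificial* data: background images (here,
procedural cardiac-like phantoms with blood-pool structures and a bright
fat-like border band; loaders for user-supplied real frames are included)
into which an artificial balloon is inserted as a 2D anisotropic Gaussian,

I′(p) = I(p) + a · I(c) · exp(−d²(p)/2),

with σx, σy ∈ {1.5, 2.5} px, integer rotation θ ∈ [0°, 359°], and peak
amplitude a ∈ {2, 3, 4} (200–400%) of the underlying center-pixel
intensity I(c). The ground-truth mask is the set of pixels within 1.5
standard deviations (Mahalanobis distance ≤ 1.5, a rotated ellipse). 10%
of training frames carry no balloon so the network learns to output
nothing when nothing is there.

**Segmentation.** A compact residual encoder-decoder (U-Net-style skip
connections, sigmoid output) is trained with the soft Dice loss
1 − (2Σpt + ε)/(Σp + Σt + ε) under ADAM; the delivered weights are those
of the epoch with minimum validation loss. A sigmoid activation ≥ 0.5 is
classed as balloon. Convolutions are BLAS-backed C++; the hand-derived
backward pass is verified against finite differences in the test suite.

**Tracking.** Per dynamic, predicted masks are split into 8-connected
regions, each scored by its mean underlying image intensity; the single
highest-scoring region across the three slices becomes the tip estimate
(centroid = tip coordinate). This guarantees a unique estimate per dynamic
and identifies the slice containing most of the balloon when it straddles
two slices.

**Evaluation.** TP = exactly one predicted region whose center of mass
lies in the ground-truth region; TN = nothing predicted, nothing present;
FN = catheter present, no prediction; FP = everything else. Accuracy,
sensitivity and specificity are computed per patient and averaged across
patients (unweighted).

## Worked example

```r
library(cathtrack)

# one phantom frame with an inserted balloon
phantom <- generate_phantom(c(64, 64), rng_seed = 7)
params  <- catheter_params(30, 38, sigma_x = 2.5, sigma_y = 1.5,
                           theta_deg = 40, amplitude_pct = 300)
frame <- simulate_catheter(phantom, params)
sum(frame$gt_mask)
#> [1] 27

# the full scaled study: generate 320 semi-artificial training frames,
# train 40 epochs, evaluate on 60 held-out dynamics (~4 min on one core)
study <- run_demo_study(seed = 1)
study$report
#> <metrics_report>
#>   60 units over 4 patients
#>   accuracy     98.3 % (sd 2.9)
#>   specificity  95.8 % (sd 7.2)
#>   sensitivity 100.0 % (sd 0.0)
mean(study$report$outcomes$tip_error_px, na.rm = TRUE)
#> [1] 0.1736416
```

The report says that on 60 held-out dynamics from four unseen phantom
subjects every balloon was detected in the correct place (per-patient
sensitivity 100%), one catheter-free dynamic produced a false detection
(specificity 95.8%), and on correct detections the estimated tip centroid
landed within a fraction of a pixel of the true balloon center.

Per-patient metrics aggregate the way the clinical evaluation reports
them — each patient weighted equally:

```r
aggregate_patients(reference_patient_metrics)
#> # A tibble: 3 × 4
#>   metric       mean    sd n_patients
#>   <chr>       <dbl> <dbl>      <int>
#> 1 accuracy     98.4 1.93           7
#> 2 specificity  99.9 0.245          7
#> 3 sensitivity  95.4 5.53           7
```

`tidy()`, `glance()` and `autoplot()` methods are provided for trained
models (loss curves) and evaluation reports (per-patient metrics). A thin
command-line front end is installed at `inst/cli/catheter-track`
(`catheter-track all --config config.yaml`); `run_pipeline()` is the same
workflow as a function.

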