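---
title: "Demographic prediction from whole-body PET MIPs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demographic prediction from whole-body PET MIPs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Patient misidentification in the imaging workflow — a study filed under the
wrong record, or a record swapped between patients — is rare but severe.
Whole-body FDG-PET carries enough anatomical and metabolic information to
predict basic demographics (sex, age, body weight) directly from the
images. If the prediction disagrees with the claimed record, the study
deserves a second look *before* it reaches the archive. `mipguard`
implements that guard: multi-angle maximum-intensity projections (MIPs)
rendered from the SUV volume, a small convolutional network per task,
patient-level aggregation, and an alert engine that compares predictions
against the claimed record.

Because clinical PET volumes cannot ship with a package, `mipguard` includes
a synthetic whole-body phantom generator. It is first-class, tested code:
every end-to-end result the package reports is computed on phantom cohorts.

## The pipeline

1. **Volume**: a nonnegative 3-D SUV grid with voxel spacing; axis order is
   (x, y, z) with z craniocaudal, slice 1 superior; +y posterior.
2. **Projection**: the volume is rotated about the craniocaudal axis
   (angles counterclockwise viewed from superior; trilinear interpolation,
   which reduces to bilinear in-plane because z is fixed) and the maximum
   is taken along the ray direction. Out-of-support samples contribute 0.
3. **Windowing**: SUV 0–10 display window, `clip((v - 0)/10, 0, 1)`; any
   uptake at or above 10 saturates (notably the brain). Windowing precedes
   resampling — the order is a package choice; the two operations commute
   except through interpolation of clipped values.
4. **Resampling**: bilinear to 64 × 64 with aspect-preserving letterboxing
   (the longer physical side fills the frame; the shorter is centered with
   zero fill) so body proportions are never distorted.
5. **View schedules**: scanner 1 contributes 19 views, scanner 2
   contributes 36. The schedules (10° steps over [0°, 180°] and
   [0°, 350°] respectively) are the only uniform single-step schedules
   producing those counts; they remain configurable per profile.
6. **Classifier/regressors**: one small CNN per task (below).
7. **Aggregation**: per-image argmax votes, patient label by majority; the
   median of per-image estimates for age/weight (robust to occasional bad
   views). Ties, possible only with an even view count, break toward the
   larger mean class probability and are flagged low-confidence.
8. **Alerts**: sex mismatches always alert; age/weight alert outside
   configurable tolerances (defaults ±10 years and ±6 kg, the bands within
   which nearly all patients are recovered). A missing claimed field yields
   an explicit "unverifiable" status, never a silent pass.

## The network

The architecture is deliberately small: four 3 × 3 convolutions (stride 1,
"same" padding), ReLU activations, three 2 × 2 max-pooling stages (each
reduces the spatial element count to a quarter; a 64 × 64 input reaches the
head as 8 × 8 maps), local response normalization, one dense hidden layer
with dropout, and either a softmax pair (sex) or a single unbounded linear
output (age or weight):

$$F(x_i) = \frac{\exp(x_i)}{\sum_j \exp(x_j)}$$

evaluated with max-subtraction for numerical stability.

Defaults and their rationale (all configurable via `network_spec()`):

* **Filters 8/16/16/32, dense 64.** The phantom task is low-entropy
  compared with clinical data; this capacity trains on a single CPU in
  minutes and saturates the synthetic tasks. Larger stacks plug in via the
  same spec.
* **Dropout 0.5** after the hidden dense layer, disabled at inference.
* **LRN** radius 2, α = 10⁻⁴, β = 0.75, bias 1 — the classical
  parameterization. Its placement is not uniquely determined by the
  architecture description; `mipguard` defaults to *after the first
  pooling stage* (placement before pooling is available via
  `lrn_position = "after_conv1"`; with the default α the two are nearly
  indistinguishable, and the post-pool position costs a quarter of the
  arithmetic).
* **Losses**: cross-entropy for sex; mean squared error on internally
  standardized targets for the regressions (predictions return in years or
  kg).
* **Optimizer**: Adam. Training monitors the loss on a held-out
  **validation split of 15 % of training patients** — the split is by
  patient, so no patient's views straddle train/validation — and stops
  when validation loss fails to improve for `patience` consecutive epochs,
  restoring the best epoch's weights. The early-stopping controller is a
  pure state machine (`early_stop_update()`), testable in isolation.
* **Backbone hook**: `build_model()` consumes any `network_spec`; deeper
  residual-style backbones are out of scope, but the spec boundary is the
  documented extension point.

The forward and backward passes (im2col convolution, pooling argmax
routing, LRN and its exact gradient) are implemented in compiled code and
verified against central finite differences in the test suite; training is
bit-reproducible under a seed.

## Augmentation

Training folds only — validation and test images are never augmented, and
augmentation happens strictly after the patient split. The default factor
of 5 keeps the unmodified original plus four independently randomized
transforms: rotation up to ±10°, zoom 0.9–1.1, translation up to ±4 px,
and additive Gaussian noise (σ = 0.02 gray units, applied after
windowing). Magnitudes are package choices (the identity always lies
inside every range) and every output records its source image and
transform parameters.

## The phantom generator

Stylized, not anatomical: stacked elliptical cross-sections (head, chest
with low-uptake lungs, abdomen, pelvis, two thighs) at soft-tissue SUV 0.8,
plus organ components. Only the *statistical* structure matters — where the
demographic signal lives and how strong it is:

* **Brain** at SUV 12: above the 0–10 window, so it saturates after
  windowing and carries no usable signal — mirroring whole-body FDG
  practice.
* **Sex**, pelvic band: males get a central focal pelvic uptake whose
  amplitude is normalized at generation time so that the male–female
  difference in pelvic-band mean SUV equals exactly the configured
  amplitude (0.05 SUV by default, which makes the focal component
  saturate); females get two lateral foci at a fixed saturating uptake
  whose display-clipped projection footprint roughly matches the male
  blob's. The sex signal in the *windowed image* is therefore the shape
  of pelvic uptake, not global brightness — so a mean-fill mask over the
  pelvis genuinely removes it (the masking ablation depends on this).
  Both sexes share a bladder at SUV 8. The noise-free pelvic-band *peak*
  separates the sexes perfectly (the normalized male uptake strictly tops
  the female foci), which is the oracle the training tests rely on; the
  band *mean* separates at matched habitus by the designed amplitude.
* **Sex**, chest band: females draw an anterior chest amplitude from
  N(0.8, 0.8) truncated at zero (males N(0.1, 0.1)) — a deliberately
  weak, high-variance secondary signal emulating inter-individual
  variability of chest uptake.
* **Age**: a paraspinal rod spanning chest and abdomen with SUV
  1.5 + 0.055 · age — a monotone intensity code (vascular/degenerative
  uptake increasing with age is the loose physical motivation).
* **Weight**: silhouette half-widths scale with √(weight/70); the head
  scales only weakly (∝ (weight/70)^0.1). No empirical weight
  distribution was available, so weight is drawn from invented
  sex-conditional normals (male 70 ± 12 kg, female 58 ± 11 kg, clipped to
  [20, 150]).
* **Demographics**: sex Bernoulli(0.56 male), age normal 61.6 ± 16.2 years
  clipped to [2, 92] — the composition of the clinical cohort this
  simulator stands in for.
* **Scanners**: profile 1 — 168 × 168 matrix, 4.1 × 4.1 × 2.0 mm voxels,
  19 views, noise scale 0.05; profile 2 — 144 × 144, 4.0 × 4.0 × 4.0 mm,
  36 views, noise scale 0.15. The differing noise plants a genuine domain
  shift for cross-scanner experiments. Default cohort mix is 87.3 % / 12.7 %.
* **Noise**: Poisson-like (σ ∝ √(SUV + 0.1)) scaled by the profile's noise
  scale, applied inside the body support; air stays exactly zero. This is
  a qualitative stand-in for reconstructed-PET noise — no attenuation,
  scatter or reconstruction physics is simulated.
* **Coverage**: vertex to mid-thigh, 1000 mm, with fractional bands head
  [0, 0.15), chest [0.15, 0.40), abdomen [0.40, 0.60), pelvis
  [0.60, 0.85), thigh remainder.

What passing tests on phantoms do *not* show: robustness to real
anatomical variability, pathology (high-uptake tumors can dominate a MIP),
arm position, tracer dose and uptake-time effects, or reconstruction
differences beyond voxel grid and noise level. The phantom demonstrates
that the *pipeline* recovers planted signal; clinical performance is a
claim about clinical data only.

## Interpretation experiments

* **Masking ablation**: horizontal bands in image coordinates (head
  [0, 0.15), chest [0.15, 0.40), abdomen [0.40, 0.60), pelvis
  [0.60, 0.85) of image height; upper body = head ∪ chest, lower body =
  abdomen ∪ pelvis; the thigh remainder is never masked). Band fractions
  are package defaults chosen to match the phantom's region layout — with
  letterboxed whole-body images the two coordinate systems coincide. The
  fill is each image's own original mean, recorded on the image so
  re-masking is idempotent. Masks are applied to training *and* test
  images, and each row of the ablation table is retrained from scratch
  under identical seeds, so differences are attributable to the masked
  region alone.
* **Grad-CAM**: channel weights are spatial means of the gradient of the
  target-class logit with respect to the last convolutional layer's
  post-ReLU maps; the rectified weighted sum is bilinearly upsampled to
  64 × 64 and max-normalized. The last conv layer is the package default
  target (the standard choice).

## Experiment designs

* **Mixed-split**: all patients pooled, 70/30 split *by patient*
  (training size ⌊0.7 n⌋), repeated (default 5×) with per-repeat seeds
  derived from a master seed by a documented splitter; each repeat
  re-draws the split. Metrics are summarized as mean ± sample SD (n − 1);
  a single repeat reports SD as NA rather than fabricating one.
* **Cross-scanner**: train on all patients of one scanner, test on all of
  the other; no split beyond validation monitoring.
* Every experiment records a manifest (design, seeds, sizes, package
  version) sufficient to reproduce it.

## Numerical choices

* `cospi`/`sinpi` drive all rotations, so axis-aligned angles are exact —
  a single-voxel volume projects to a single exact pixel at 0°, and the
  90° projection matches a transpose/flip oracle to machine precision.
* The MIP projector skips sample points outside the volume's in-plane
  support radius (rotation preserves radius, so the skipped samples are
  provably zero; the optimization never changes the result).
* Max-pooling ties route the gradient to the first maximum in scan order.
* Regression targets are standardized inside `train()`; the model stores
  center/scale and always reports original units.
* Degenerate inputs error loudly: empty volumes, degenerate SUV windows,
  empty vote sets, single-scanner cohorts in cross-scanner designs,
  non-finite losses during training.

## Problem sizes used by the shipped checks

The package's own end-to-end checks (test suite and
`scripts/acceptance.R`) run on an 80-patient cohort at the default scanner
mix, plus a dedicated 40-patient scanner-1 cohort for the seven masking
retrainings — sizes at which the planted signals are comfortably
recoverable on a single CPU. The masking cohort plants the sex signal in
the pelvis *only*: weights are drawn sex-independently and the chest
feature is disabled there, so the Bayes-optimal classifier on
pelvis-masked images is chance-level and the ablation has a known answer.
(In the default cohort, habitus itself carries sex information through the
sex-conditional weight model, exactly as in clinical populations.) The
designed recovery bands asserted in the checks are ±10 years for age and
±10 kg for weight (the weight→habitus mapping is the coarsest of the three
signals); the alert tolerances remain ±10 years / ±6 kg.

## Known limitations

* The phantom's weight→habitus and age→intensity mappings are invented;
  they make recovery *possible*, not clinically calibrated.
* A 64 × 64 MIP discards fine structure; the resampling is plain bilinear
  (no anti-alias prefilter), as in the windowing/resampling contract.
* The CNN runs on CPU in double precision; no GPU path is provided.
* Tie behavior in patient-level voting is a documented package convention;
  with the odd 19-view schedule ties cannot occur at all.
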