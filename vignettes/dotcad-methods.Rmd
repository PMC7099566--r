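---
title: "Classifying breast lesions in diffuse optical tomography volumes: models and methods"
author: "dotcad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying breast lesions in diffuse optical tomography volumes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Diffuse optical tomography (DOT) reconstructs maps of tissue optical
absorption from near-infrared measurements. Because hemoglobin dominates
absorption at these wavelengths and malignant lesions are hypervascular,
DOT offers endogenous, non-ionizing contrast for breast imaging — and it is
insensitive to breast density, where mammography struggles. Its weakness is
spatial resolution: reconstructed lesions are diffuse, low-contrast blobs,
hard for a human reader to classify.

`dotcad` implements a computer-aided diagnosis pipeline for this setting: a
small convolutional neural network, written from scratch (no deep-learning
framework), that classifies benign versus malignant lesions from axial
slices of 91 × 91 × 31 voxel DOT absorption volumes. Because the clinical
cohort the pipeline was designed around is private, the package also ships
a synthetic phantom generator so that every stage — preprocessing, network,
training, evaluation — is testable end to end at the cohort's scale (43
benign and 20 malignant volumes).

## The phantom model

Nothing generative is known about the original data beyond its grid, class
proportions, tumor depth range, and example tumor extents, so the phantom
is this package's own model. Each volume is built in five steps:

1. **Breast support.** An ellipse in the transverse plane whose radii taper
   with depth as $\sqrt{1 - 0.8\,((z-1)/(n_z-1))^2}$, a pendant breast
   narrowing away from the chest wall. Voxels outside the support are
   exactly zero.
2. **Background.** Baseline absorption $\mu_0 = 1$ (arbitrary units)
   modulated by correlated Gaussian noise: white noise smoothed with a
   3-voxel Gaussian, standardized, and applied at 5 % fractional amplitude.
   This emulates fibroglandular heterogeneity. Absolute units are
   irrelevant downstream because every slice is min–max normalized.
3. **Inclusion.** Exactly one lesion per volume, its center drawn uniformly
   on the axial index range 6–25 (where clinical tumors concentrate).
   Semi-axes are drawn in centimetres — $a \in [1.0, 1.6]$,
   $b, c \in [0.5, 0.8]$ — matching example clinical extents of about
   3.0 × 1.3 × 1.3 cm, and converted to voxels at 2.0 mm pitch (so the
   91-voxel transverse field spans ~18 cm). Benign lesions are single
   smooth ellipsoids with multiplicative contrast drawn from 1.3–1.8×
   background; malignant lesions are unions of four overlapping ellipsoidal
   lobules (irregular margins) with contrast from 2.0–3.0×. The disjoint
   contrast ranges are the separability knob: with them, the default cohort
   is learnable but not trivial.
4. **Point-spread blur.** The whole field is smoothed with an anisotropic
   Gaussian, default $\sigma = (6, 6, 12)$ mm. DOT resolution is of order
   5–10 mm transversely and substantially poorer in depth; the strong axial
   smearing is what makes *whole-volume* slice labelling meaningful — a
   lesion's signature bleeds into essentially every plane of the sliced
   range, as it does in clinical reconstructions. An earlier isotropic
   6 mm choice left distal slices of a lesion with no class signal, which
   contradicts the clinical observation that slice-level classification
   works; the anisotropic default restores that property and is the
   documented rationale for it.
5. **Masking.** The support mask is reapplied and negatives clipped, so all
   voxels are non-negative and the exterior is exactly zero.

Per-volume seeds are derived from a single cohort seed, making every volume
individually reproducible from the manifest.

**What the phantom does not emulate:** reconstruction artifacts of a real
finite-element inverse solver, scattering or hemoglobin channels,
bilateral asymmetry, chest-wall signal, and inter-patient covariance
structure. A green benchmark therefore establishes that the pipeline can
recover a contrast-plus-shape class difference at clinical scale and noise
— not clinical performance.

## Preprocessing

Each volume contributes the 20 axial planes with indices 6–25 (1-based,
inclusive). Each plane is resized to 32 × 32 by corner-aligned bilinear
interpolation (outputs are convex combinations of the four nearest inputs,
so the value range never expands) and min–max normalized to $[0,1]$; a
constant plane maps to zeros by convention. 63 volumes thus yield 1260
images.

The train/test split is stratified *per class at the image level*: within
each class, images are shuffled and the first
$\mathrm{round}(0.75\,n_{\text{class}})$ (half away from zero) go to
training. This reproduces the published counts exactly — 645 benign + 300
malignant training and 215 + 100 test images — but lets slices of one
patient straddle the split. Because that leakage may be undesirable, a
patient-level mode (`by = "patient"`) assigns whole patients to one side;
it cannot reproduce the exact image counts. Neither granularity is
documented for the original protocol; the image-level default is the one
consistent with the published table.

Class imbalance is addressed by flip augmentation: every malignant
*training* image is duplicated as its left–right mirror (a deterministic,
anatomically plausible choice among the unstated flip axes), growing
training from 945 to 1245 images. The test set is never augmented.

## The network

```
32×32×1 → conv 6@5×5 (stride 1, valid) → BN → sigmoid → avgpool 2×2 → 14×14×6
        → conv 12@5×5               → BN → sigmoid → avgpool 2×2 → 5×5×12
        → flatten (300) → fully connected (300×2) → softmax
```

Design choices where the source architecture is under-specified:

* **Convolution as cross-correlation** (no kernel flip) — universal for
  learned filters, where the distinction is unobservable.
* **Batch normalization placement** conv → BN → sigmoid → pool, following
  the textual order of the description; $\varepsilon = 10^{-5}$; running
  statistics by exponential moving average with retention 0.9; biased
  (1/N) batch variance. Training mode requires batches of at least two
  images; inference always uses running statistics, so a score depends
  only on the parameters and the image, never its batch companions.
* **Output layer**: the "simple logistic classifier" is realized as a
  2-unit softmax with cross-entropy loss over the one-hot codes
  (1,0) = malignant, (0,1) = benign; softmax over two units and a single
  logistic unit are equivalent parameterizations, and softmax keeps the
  one-hot bookkeeping explicit. Ties at score 0.5 resolve to benign
  (the conservative fixed rule).
* **Initialization** (unstated in the source): uniform fan-in scaled,
  $U(\pm\sqrt{3/\text{fan-in}})$, giving unit-variance preactivations that
  keep the sigmoids unsaturated; biases 0; BN at identity. Fully
  deterministic per seed.
* The layer bookkeeping "8-layer" versus "five learned layers" in the
  source is internally inconsistent; the architecture itself is
  unambiguous (learned: two conv, two BN, one FC) and is what the package
  asserts (32→28→14→10→5→300→2).

All forward and backward passes are hand-written and verified against
central-difference gradients; convolution's im2col gather/scatter lives in
a small C++ file for speed, with the arithmetic done by BLAS.

## Training and evaluation

Mini-batch SGD with classical momentum
($v \leftarrow m v - \eta g$, $p \leftarrow p + v$), defaults
$\eta = 0.3$, batch 83, momentum 0.9 (unstated in the source; the standard
value), at most 500 epochs. The training set is reshuffled each epoch with
a seeded generator; a final short batch is kept when it has ≥ 2 images
(batch-norm is defined) and dropped when it is a singleton.

Early stopping monitors the misclassification rate (MCR) of a monitor set
after every epoch and stops once `patience` epochs pass without strict
improvement, restoring the best-epoch weights (ties → earliest). The
source states only that training is "terminated if no progress is noted"
and that the monitored minimum arrives "after approximately 200 epochs";
the default patience here is 100 epochs. The choice matters: an MCR
estimated each epoch on a few hundred images under this high learning
rate swings by several percentage points, so one lucky early epoch can
set a record that genuine convergence needs many epochs to beat. On the
package's own benchmark, a patience of 50 terminated the augmented
training at epoch 120 (best epoch 70, test AUC 0.874) while the identical
run allowed to continue converged at best epoch 245 with AUC 0.995 —
patience must span those noise excursions for the stopping rule to detect
convergence, which is what the ~200-epoch horizon reported for the
original experiment implies. Following the original protocol the *test*
set is the monitor — methodologically leaky, and stated as such; pass any
held-out set as `monitor_set` for honest model selection.

Evaluation reports the 2 × 2 confusion matrix (malignant positive),
sensitivity, specificity, accuracy (metrics with an absent denominator
class are `NA`, not 0), and the ROC curve swept over all distinct scores
with sentinel endpoints (0,0) and (1,1). AUC is the trapezoidal integral,
which with tie-grouped points equals the Mann–Whitney statistic with half
credit for ties — asserted against an independent $O(n^2)$ pairwise oracle
in the tests. A learning-rate sweep (default grid 0.03, 0.1, 0.3, 1.0, 3.0
bracketing the source's best rate by half-decades — the original five-rate
grid is unpublished) and class-stratified k-fold cross-validation
(round-robin assignment; the held-out fold doubles as the early-stopping
monitor; per-fold mean ± sd reported) mirror the published robustness
checks.

## Numerical and degenerate-input conventions

* Min–max of a constant image → all zeros; normalization is idempotent.
* Cross-entropy clamps the true-class probability at $10^{-12}$.
* Sigmoid saturates cleanly (IEEE overflow gives exact 0/1, no error).
* `round(0.75 n)` uses round-half-away-from-zero, exact for the published
  counts.
* Gradient checks compare with a floored relative error: convolution
  biases are exactly cancelled by the following batch normalization, so
  both analytic and numerical gradients are ~0 and a raw relative error
  would only amplify round-off.
* Axial indices are 1-based and ranges inclusive throughout ("6 to 25" =
  20 slices).

## Reproducibility

Every stochastic step — cohort generation, per-volume rendering, the
split, initialization, epoch shuffling — is driven by explicit seeds, with
child seeds derived deterministically from a single master seed (always
below $2^{31}$). Two runs from the same configuration produce byte-identical
reports; the run directory written by `run_pipeline()` stores its own
configuration and can be reproduced from it exactly.

## Known limitations

* The published clinical numbers (90.2 %/93.3 % accuracy, AUC 0.94/0.95)
  were measured on a private cohort and are not reproducible here; the
  synthetic separability benchmark (test AUC ≥ 0.90 on the default
  cohort) is the package's stand-in, and it certifies pipeline capability,
  not clinical validity.
* Image-level splitting (the default, count-exact mode) leaks patients
  across partitions; use `by = "patient"` for honest generalization
  estimates on the phantom.
* Monitoring the test set for early stopping (the reproduced protocol)
  biases test metrics optimistically.
* The CNN is a fixed 32 × 32 single-channel architecture; there is no 3-D
  convolution, no scattering/hemoglobin channels, and no dropout (batch
  normalization stands in as the regularizer).
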