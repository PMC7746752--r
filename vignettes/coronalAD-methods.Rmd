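---
title: "Methods: coronal-slice classification of Alzheimer's disease"
author: "coronalAD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coronal-slice classification of Alzheimer's disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
`coronalAD`: what the pipeline models, why each default is what it is,
what the synthetic phantoms do and do not emulate, and where the design
was genuinely open.

## The problem and the modelling idea

Medial temporal lobe (MTL) atrophy — shrinkage of the hippocampus and
adjacent structures — is the canonical structural-MRI signature of
Alzheimer's disease (AD). Rather than feeding whole 3D volumes to a
classifier, the pipeline extracts a band of 2D coronal slices covering
the MTL from each rigidly template-aligned T1-weighted volume, classifies
every slice independently with a convolutional network that also sees the
subject's age, sex and the slice's position, and averages the slice
probabilities into a subject-level AD probability. Rigid (6-parameter)
alignment is used throughout because it cannot change brain morphology:
the atrophy signal the classifier must detect is preserved exactly.

The subject-level decision chain is: per-slice softmax probability →
mean over the slices of a subject → mean over the five cross-validation
fold models. Averaging is permutation-invariant and keeps each fold model
an independently validated classifier.

## The phantom generator: the study conditions

Clinical T1 volumes cannot ship with a package, so every stage is
developed and tested against a synthetic cohort whose ground truth is
known exactly. A phantom head is a set of nested ellipsoids, fixed in
millimetre units (the grid and voxel spacing only control sampling):

* scalp/skull shell, intensity 1.0 (semi-axes 68 × 81 × 61 mm outer,
  62 × 75 × 55 mm inner);
* brain parenchyma, intensity 0.6 (54 × 67 × 47 mm);
* a dark ventricle, intensity 0.3 (16 × 30 × 10 mm, centred 8 mm
  anterior and 8 mm superior of the head centre);
* two bilateral medial-temporal ellipsoids, intensity 0.8
  (10 × 15 × 8 mm semi-axes at (±28, −10, −15) mm), the class-informative
  structure.

The intensity convention (background 0, shell brightest, MTL brighter
than surrounding parenchyma, dark CSF-filled ventricle) is chosen so that
Otsu thresholding and per-slice min–max normalization behave as they do
on real T1 images. Surfaces are rendered with a one-voxel partial-volume
ramp. This matters beyond realism: hard-edged ellipsoids alias on the
sampling grid, and that aliasing is grid-locked in both the subject and
the template, which biases an intensity-based registration toward
grid-aligned poses. The distinct semi-axes per axis and the off-centre
ventricle make all three rotations identifiable to the
mean-squared-difference metric.

For an AD subject the MTL volume is multiplied by
`1 − atrophyEffect` (default 0.3, a typical hippocampal volume loss in
mild AD); every subject additionally receives lognormal volume jitter
(sdlog 0.05). Nuisance factors are a uniform random rigid misalignment
(default ±8° and ±8 mm per axis, representative of head-positioning
variability) and additive Gaussian noise with SD 8% of the parenchyma
intensity. Ages are drawn from a truncated normal (74.6 ± 7 years,
55–95) and sex with 46.7% women, identically in both classes — an
age/sex-matched design, so the metadata channel carries no class signal
in the phantom study. Generation is a pure function of the specification
and seed.

What the phantoms deliberately do **not** model: MR physics (bias
fields, multi-site scanner differences), anatomical variability beyond
size jitter, and any atrophy outside the MTL. Passing tests on phantoms
therefore demonstrates that the pipeline machinery — alignment, slice
selection, learning, ensembling, statistics — recovers a known
medial-temporal effect; it does not certify clinical accuracy.

## Template and anchor

The registration template is the voxelwise mean of CN phantoms aligned
to a reference. By default the reference is the first input volume; the
phantom wrapper instead aligns to the canonical (unmisaligned,
noise-free) phantom so that template space coincides with the
generator's standard space — the analogue of an external population
template. The anchor coronal index marking the start of the
medial-temporal slice range is stored as template metadata, computed
analytically from the generator geometry as the posterior-most extent of
the MTL ellipsoids (index 103 on the 256-voxel 1 mm grid, 35 on the
96-voxel 2 mm grid). A real deployment would set this anchor once on the
template by anatomy (the hippocampal body at the level of the anterior
pons); a phantom encodes that anatomy exactly, so detection would be
circular.

The slice range spans 30 mm of anatomy: 30 slices at 1 mm spacing, 15 at
the desk-scale 2 mm spacing. The slices proceed posterior-to-anterior
from the anchor (the direction is configurable; the anatomical
description fixes only the starting point).

## Registration

`registerRigid` minimises the mean intensity squared difference (the
appropriate metric when moving and fixed share an intensity convention,
as phantoms do; mutual information would be the choice for multi-site
real data and is noted as out of scope). The search runs over a
two-level block-mean pyramid (shrink 4, then 2) with L-BFGS-B and the
analytic gradient of the metric with respect to the six parameters.
Rotations are internally rescaled (1 unit = 5°) so the six directions
are comparably conditioned. The optimiser is initialised from intensity
moments — centroid shift for translation, matched principal axes for
rotation (signs resolved toward identity) — which places the start well
inside the convergence basin for the misalignment ranges the phantoms
use. Non-convergence within the iteration budget is flagged in the
result; the best-so-far transform is still returned.

The second alignment pass (skull-stripped volume to skull-stripped
template) starts from identity at the finest level only: after the first
pass the volume is already coarsely aligned, and the refinement's role is
to remove the residual bias the scalp/skull introduced.

Expected accuracy under the default conditions, measured by composing
the recovered transform with the inverse of the applied one: median
rotation error well under 1° and translation error around 0.1 mm, with
occasional outliers along the least-identifiable rotation axis.

## Brain extraction

A deterministic morphological extractor stands behind the brain
extraction interface: Otsu threshold on the volume histogram, binary
opening (box radius 1 voxel) to detach the shell, largest 6-connected
component, closing (radius 2) to smooth the boundary, and masking. On
noise-free phantoms it recovers the brain ellipsoid with Dice above
0.95. The dark ventricle falls below the threshold and is excluded from
the parenchyma mask, which is the behaviour of a tissue mask rather than
an intracranial-volume mask; registration is unaffected because the
surrounding parenchyma dominates the metric. The interface is the
contract; a learned extractor could be swapped in without touching any
downstream code.

## The classifier

The bundled backbone, `tiny_cnn`, is a three-stage convolutional network
(8/16/32 channels of 3 × 3 kernels, batch normalisation with fused ReLU
after each convolution, 2 × 2 max pooling per stage, then a fully
connected map to the feature vector). It honours the same
feature-vector contract as a large backbone: with the default
`featureDim = 1024` the concatenated feature-plus-metadata vector has
1027 entries; the desk-scale configuration uses 64 features. Batch
normalisation is what makes from-scratch training converge within a few
hundred SGD updates at the fixed base learning rate of 0.001 — the
reference training recipe assumes a pretrained backbone, which is out of scope, so
the architecture must supply the optimisation conditioning instead.

Metadata are scaled onto the feature scale: age / 100, sex ∈ {0, 1},
slice number / n. Without scaling, an age of ~75 would dwarf the
unit-scale features at a shared learning rate.

Inputs to the backbone are centre-cropped to 48 native pixels (96 mm,
comfortably containing the brain) and resized to 32 × 32. The crop
removes empty background that carries no class information; at the
desk-scale grid this keeps the MTL cross-section several pixels wide,
which the 256-voxel configuration achieves natively.

Training follows the fixed recipe: shuffled mini-batches of 64 slices,
SGD with Nesterov momentum 0.9 (the conventional value; the momentum
coefficient is not part of the stated recipe), weight decay 5e-5
applied to all parameters, base learning rate 0.001 decayed by 0.1 on a
validation-loss plateau (relative tolerance 1e-4; patience 5 epochs at
desk scale, where the small validation set makes the loss noisy) and at
most three decays. Early stopping triggers when the 5-epoch moving
average of subject-level validation accuracy improves by no more than
5e-4 over the last 5 epochs; the check begins once two full windows
exist, because a from-scratch network can sit at chance for the first
few epochs while the loss is already falling. Validation accuracy is
subject-level (slice probabilities averaged per subject), consistent
with the averaged probability being the subject's prediction. The
weights of the best-validation-accuracy epoch are retained. The loss is
standard binary cross-entropy with probabilities clamped at 1e-7.

Augmentation applies, in a fixed order (rotation, scale, translation in
one bilinear warp; then contrast `c(v − 0.5) + 0.5`; then gamma `v^γ`),
parameters drawn uniformly per slice from configured ranges, to training
slices only. The general defaults are mild geometric/intensity ranges
(±10°, scale 0.9–1.1, ±8 px, contrast and gamma 0.8–1.2). The
desk-scale experiment configuration uses tighter ranges (±5°, 0.95–1.05,
±2 px, 0.9–1.1): augmentation exists to cover nuisance variation the
aligned data actually exhibit, and phantom registration residuals are
an order of magnitude smaller than clinical ones; in particular a ±10%
scale augmentation would be the same order as the ~11% linear size
difference that constitutes the class signal.

## Evaluation protocol

Each trial: class-wise 80/20 development/test split (floor on the
development count, so 195 + 195 gives 156 + 156 and 39 + 39); stratified
five-fold partition of the development set (round-robin per class, so
fold validation counts differ by at most one); one classifier per fold;
the five-model ensemble evaluated on the held-out test set
(within-dataset) and, when a second dataset is supplied, on that dataset
in its entirety (between-dataset), with no recalibration. Trials repeat
with seeds derived deterministically from the master seed (seed + trial
index). Aggregation is mean and sample SD over trials; within- versus
between-dataset metrics are compared with a paired t-test over trials.

A noted ambiguity: the ensemble could be read as the five fold models of
one cross-validation or as five repetitions of the whole
cross-validation. The five-fold-model reading is implemented; the
repetition count is exposed as the number of trials.

Operating points are chosen by Youden's index (J = sensitivity +
specificity − 1), ties broken at the lowest threshold, with accuracy
counted at that threshold. AUC variance and comparisons use DeLong's
estimator (via pROC), and the AUC confidence interval is the normal
approximation AUC ± z·SE truncated to [0, 1] — the CI method behind the reference
results is not stated, so the method is recorded in the output.

## Desk-scale problem sizes

The default configuration runs the full protocol at sizes chosen to keep
an end-to-end experiment in minutes on one CPU while leaving every
mechanism intact: 96-voxel 2 mm phantoms (the full-resolution 256-voxel 1 mm
configuration remains available), 60 + 60 subjects, 15 slices (the same
30 mm span), 64-feature backbone on 32 × 32 crops, 15-epoch budget with
early stopping, 3 trials. Under these conditions the within-dataset test
AUC averages well above 0.85 at atrophy effect 0.3, and sits near 0.5
when the effect is zero — the null check that the pipeline cannot invent
signal. The zero-effect mean over a few trials is itself noisy (test
sets of 12 + 12), hence the wide nominal band around 0.5 used in tests.

## Numerical choices and degenerate inputs

* Min–max normalization maps a constant slice to all zeros (the
  convention that avoids 0/0); it is idempotent.
* Trilinear interpolation for volumes and bilinear for slices, zero
  outside the field of view; masks use hard thresholds, never
  interpolated fractions.
* Rigid transforms are composed and inverted through homogeneous
  matrices; the linear part always has determinant 1 up to floating
  point.
* The loss clamps probabilities at 1e-7; a "perfect" prediction
  therefore has loss ~1e-7, not exactly 0.
* An empty brain mask (all-zero or constant volume) is an error, not a
  silent empty result.
* Probability ties in the Youden sweep resolve to the lowest threshold;
  equal validation accuracies keep the earlier epoch's weights.
* All randomness flows from explicit seeds; per-subject and per-trial
  seeds derive from the master seed by a fixed affine map modulo
  2^31 − 1, so any subject or trial can be regenerated in isolation.

## Known limitations

* The phantom's rigid-misalignment model cannot probe nonlinear
  anatomical variability; registration accuracy on real heads will be
  worse and metric choice (mutual information) becomes relevant.
* The morphological brain extractor assumes a bright shell separated
  from the parenchyma by a gap; real necks, eyes and dura violate this
  and motivate learned extractors.
* The tiny backbone is a stand-in honouring the architectural contract;
  absolute classification performance on clinical data is out of scope,
  and pretrained large-backbone weights are not bundled.
* The early-stopping and plateau rules act on small validation sets at
  desk scale and are accordingly noisy; their thresholds are
  configurable.
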