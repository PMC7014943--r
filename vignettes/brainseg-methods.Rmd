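---
title: "Methods: a 3D residual refinement network for brain lesion segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a 3D residual refinement network for brain lesion segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Brain lesions — glioma tissue compartments (necrotic core, oedema,
non-enhancing and enhancing core) or ischemic stroke outcome masks — must be
delineated voxel by voxel from several co-registered MRI modalities (T1,
T1-contrast, T2, FLAIR for tumors; ADC and perfusion maps such as TTP, Tmax,
rCBV, rCBF, MTT for stroke). Manual delineation is slow and inter-rater
variable; the package implements a single-pass, fully-convolutional 3D
network that predicts a class for every voxel of the input grid, together
with the training strategy, windowing and evaluation machinery that make the
model trainable and testable end to end.

All volumes are plain R arrays in `[x, y, z]` order (the NIfTI on-disk
layout); the slice axis is the third dimension; multi-modality stacks add a
fourth, modality, dimension. Voxel spacing is carried as metadata only — the
method operates on voxel grids.

## The model

`seg_config()` / `build_model()` realize a compact 3D residual encoder with
a refinement decoder:

* **Encoder.** Four blocks of 3×3×3 convolutions with channel widths
  {32, 64, 128, 256}. Block 1 is two plain convolutions; blocks 2–4 each
  begin with a strided 3×3×3 convolution (convolutional down-sampling, not
  pooling, to preserve local detail) followed by two residual units of two
  convolutions each with an identity shortcut. That is
  2 + 3 × (1 + 2 × 2) = **17 backbone convolutions**, each followed by batch
  normalization and a ReLU (order conv → BN → ReLU; the residual addition
  precedes the final ReLU of a unit). In-plane resolution scales by
  {1, 1/2, 1/4, 1/8} across the blocks.
* **Slice axis.** By default the down-sampling strides are `(2, 2, 1)`:
  the slice axis keeps full resolution through every layer, which preserves
  through-plane detail on anisotropic clinical scans whose slice counts
  (e.g. 155, or ~20 for perfusion studies) are small and not multiples
  of 8. Because halving *all* dimensions is also a defensible reading of the
  architecture, `depth_downsample = TRUE` realizes it; it requires slice
  counts divisible by 8.
* **Refinement decoder.** A 1×1×1 *adaptive* convolution maps every block's
  output to a constant 128 channels. Three *refine units* then fuse features
  coarse-to-fine (block 4 → 3 → 2 → 1): each branch passes a linear 1×1×1
  convolution (with bias), the coarse branch is up-sampled ×2 in the
  down-sampled dimensions, the branches are summed element-wise, and a
  3×3×3 convolution (with BN + ReLU) refines the sum. The last refined layer
  therefore holds 128 channels at exactly the input resolution.
* **Head.** A biased 1×1×1 convolution to the class count and a per-voxel
  softmax. No CRF or any other post-processing; `predict_labels()` is a pure
  argmax with ties broken toward the lower (background-favouring) class
  index.

With the default widths the model has 11,976,709 trainable parameters
(convolution weights, BN scale/shift, refine-branch and head biases) — about
12 M, an order of magnitude leaner than typical 3D encoder–decoders. The
per-layer accounting is exposed by `describe_network()` and is checked in
the test suite against an independent closed-form summation.

Width choices are free parameters: `desk_config()` keeps the identical
topology (including the 17 backbone convolutions) at widths 8/16/32/64 and
refine width 16 so that a single CPU trains it in minutes.

### Numerical choices

* Weights: He fan-in initialization, `sd = sqrt(2 / (C_in * k^3))`,
  seedable. BN: affine, `eps = 1e-5`, running-moment momentum 0.9
  (training-mode statistics pool over batch and voxels, as is standard for
  dense prediction). Biases are omitted wherever BN directly follows.
* ×2 up-sampling uses the half-voxel-centre convention
  (`pos = (o + 0.5)/2 - 0.5`, clamped at borders), trilinear by default,
  `"nearest"` configurable. Only down-sampled dimensions are interpolated.
* In-plane extents must be multiples of 8 (three exact halvings); the
  forward pass rejects anything else with an explicit message.
* The engine (chunked im2col 3D convolution, interpolation adjoints) lives
  in `src/nn_ops.cpp`; the backward pass is hand-derived and verified
  against central finite differences to ~1e-7 relative error in the tests.

## The focal loss

Dense 3D training is dominated by easy background voxels. The focal loss
re-weights each voxel's cross-entropy by `(1 - p_t)^γ`, where `p_t` is the
softmax probability of the voxel's true class:

L = mean over voxels of −(1 − p_t)^γ log(p_t)

With γ = 0 this *is* mean cross-entropy (`cross_entropy()` delegates to
`focal_loss(gamma = 0)`, bit for bit); larger γ down-weights well-classified
voxels more strongly. The published description is binary; the multi-class
form used here applies the definition per voxel to the true-class softmax
probability and averages without class weighting — the standard
generalization. The value of γ used for the published benchmark results is
not stated; the package defaults to γ = 2, the canonical choice from the
focal-loss literature, exposed in every configuration. `p_t` is clamped to
`[1e-7, 1]` before the logarithm; the analytic gradients (with respect to
probabilities, and to logits for training) are finite-difference checked.

## The training curriculum

`default_curriculum()` encodes the three stages, each a continuation of the
previous stage's weights:

| stage | augmented fraction | loss |
|-------|--------------------|------|
| 1     | 0                  | cross-entropy |
| 2     | 0.50               | cross-entropy |
| 3     | 0.75               | focal (γ) |

The full-scale regime runs 500 epochs per stage with Adam at a constant
learning rate 1e-4 and batch size 40. Open details were pinned as follows:
optimizer moments are **reset** at stage boundaries (each stage is a new
task; `reset_optimizer = FALSE` carries them over); augmentation decisions
are re-drawn every epoch; patches from all scans are pooled and shuffled per
epoch, seeded, so a fixed seed reproduces the entire loss history.

## Data augmentation

Applied to a scan with the stage's probability, in this order:

1. **Slice-level intensity jitter** — each in-plane slice of each modality
   is multiplied by an independent factor ~ U(0.8, 1.2). (Whether the factor
   is drawn per slice or per slice-and-modality is ambiguous in the source
   description; per slice-and-modality was chosen.)
2. **Rotation** by one of {0°, 90°, 180°, 270°}, identical for all slices,
   implemented as exact index permutations.
3. **In-plane rescale** by one factor from [0.5, 1.2] (the printed range
   "[0:5; 1:2]" read as a decimal-separator artifact), bilinear for images
   and nearest-neighbour for labels, then centre-cropped/zero-padded back to
   the original extent.
4. **Horizontal then vertical flip**, each with probability 0.5 (the flip
   probability is unstated; 0.5 is the symmetric choice).
5. **ROI-constrained random crop**: the crop window is sampled uniformly
   among positions containing the lesion's in-plane bounding box whenever a
   lesion is present; if the box cannot fit, the crop centres on it with a
   warning.

Labels always receive exactly the same geometric draw as the images, with
nearest-neighbour interpolation only, so the label set is never polluted.

## Windowing and inference

Scans are windowed along the slice axis (`plan_windows()`): `floor(D/d)`
non-overlapping windows plus, when `D mod d ≠ 0`, one remainder window
anchored at `D − d`. This is the unique simple rule consistent with all
three published counts — 13 windows for a 155-slice scan at depth 12,
3 windows (offsets 0, 7, 13) for a 20-slice scan at depth 7, and 5
inference sub-volumes for a 155-slice scan at depth 31. Training patches
take one ROI-constrained in-plane crop per window (12×128×128-voxel patches
in the tumor-scale configuration, 7×96×96 in the stroke-scale one);
inference sub-volumes keep the full plane. `stitch()` copies
non-overlapping slices, averages slices covered by the remainder window
(symmetric and deterministic, rather than last-writer-wins), and
renormalizes per voxel.

## Evaluation

`dice()`, `sensitivity()`, `specificity()` and `precision()` follow the
standard confusion-matrix definitions; Dice is the F-measure, and the
identity `Dice = 2·prec·sens/(prec+sens)` is exercised in the tests.
Degenerate cases are pinned to common benchmark-platform conventions: Dice
is 1 for two empty masks and 0 when exactly one is empty;
sensitivity/specificity/precision are `NA` (excluded from aggregates) when
their denominator is empty. `merge_brats_regions()` maps tissue labels to
the nested evaluation regions: whole = {1,2,3,4}, core = {1,3,4},
enhancing = {4}. Per-case scores are averaged unweighted.

## The phantom generator

`make_phantom()` produces the data the model is tested on without clinical
downloads: a brain ellipsoid positions a lesion of nested axis-aligned
ellipsoid compartments (oedema ⊃ non-enhancing ⊃ enhancing ⊃ necrotic in
glioma mode; a union of 2–3 overlapping ellipsoids as an irregular binary
stroke lesion), and voxel intensity is a per-(class, modality) table entry
plus Gaussian noise. The default table uses contrast patterns reminiscent of
T1/T1c/T2/FLAIR (e.g. enhancing bright on T1c, oedema bright on FLAIR) with
inter-class distances large relative to the default noise (σ = 3), so the
classes are separable from intensity alone — a property the tests verify by
nearest-table-row classification. `make_dataset()` jitters centres (±12% of
the half-extent) and radii (×0.85–1.1) under a per-index seeded stream, so
`n` and `seed` fully determine the data.

What the phantoms deliberately do **not** emulate: MRI physics (bias
fields, partial-volume effects, coil inhomogeneity), anatomical texture,
irregular infiltrative lesion boundaries, or inter-subject variability.
Passing tests therefore demonstrate that the implementation optimizes its
objective and recovers geometrically simple, intensity-separable lesions;
they say nothing about clinical accuracy on real scans, which is why the
published benchmark scores are out of scope here.

## Desk-scale profile and problem sizes

The test suite and examples run a named reduced profile chosen once:
`desk_config()` (widths 8/16/32/64, refine 16) with `desk_train_config()`
(patches 8×32×32, batch 2, Adam 1e-3, three stages of 20 epochs). The
learning rate is ten times the full-scale value because the desk run takes
roughly 600 optimizer steps instead of hundreds of thousands; the epoch
count sits inside the 50–200 band that suffices for the phantom task. The
end-to-end check trains this profile on four binary-mode phantoms of
48×48×16 voxels and requires whole-lesion training Dice ≥ 0.8 plus a
decreasing stage-1 loss.

## Known limitations

* No general autograd: the backward pass is specific to the fixed topology;
  exotic variants (dilated or non-local adaptive layers, 2D models) would
  need new derivations. They are intentionally out of scope.
* Training at the published scale (1500 epochs, batch 40, multi-GPU) is out
  of scope; the package trains reduced profiles on CPU.
* Skull stripping, co-registration and bias-field correction are assumed
  done upstream, as is conventional for benchmark data.
* `simulate()` draws voxels independently from the predicted class
  probabilities; it does not model spatial correlation of errors.
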