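# brainseg

Voxel-wise segmentation of brain lesions from co-registered multi-modality
3D MRI, for image-analysis researchers and methodologists working with
glioma tissue maps (necrotic core, oedema, non-enhancing, enhancing core)
or ischemic-stroke outcome masks. The package implements, in a single
trainable R object, a compact fully-convolutional 3D residual network with
a multi-level refinement decoder, the focal-loss objective for
class-imbalanced dense prediction, a three-stage curriculum with staged
data augmentation, slice-axis windowing for patch extraction and
memory-bounded sliding-window inference, overlap metrics with BRATS-style
label merging, and a synthetic phantom generator so everything runs end to
end without clinical data.

## The model

The network maps an `M`-modality volume to per-voxel class probabilities on
the same grid:

* **Encoder** — four blocks of 3×3×3 convolutions (widths 32/64/128/256),
  each followed by batch normalization and ReLU. Block 1 is two plain
  convolutions; blocks 2–4 each open with a strided down-sampling
  convolution and continue with two residual units (two convolutions plus
  an identity shortcut), giving 17 backbone convolutions and in-plane
  scales {1, ½, ¼, ⅛}. The slice axis keeps full resolution by default.
* **Refinement decoder** — 1×1×1 adaptive convolutions bring every block to
  a constant 128 channels; refine units fuse features coarse-to-fine
  (1×1×1 on each branch, ×2 up-sampling of the coarse branch, element-wise
  sum, then a 3×3×3 convolution), so the classifier head sees 128-channel
  features at the input resolution. About 12 M trainable parameters in
  total.
* **Training** — per-voxel softmax with focal loss
  `FL(p_t) = −(1−p_t)^γ log(p_t)` (γ = 0 recovers cross-entropy), Adam, and
  a three-stage curriculum: original data + cross-entropy, then 50%
  augmentation, then 75% augmentation + focal loss.

The conv/BN/upsampling engine and its hand-derived backward pass are
implemented in R and RcppArmadillo (`src/nn_ops.cpp`) and are verified
against finite differences in the test suite.

## Worked example

Train the desk-scale profile (identical topology at reduced width) on two
synthetic glioma phantoms and evaluate with the merged tumor regions:

```r
library(brainseg)

phantoms <- make_dataset(2, phantom_config(shape = c(48, 48, 16)), seed = 1)

fit <- brainseg(phantoms,
                model = desk_config(n_modalities = 4, n_classes = 5),
                control = desk_train_config(seed = 1))
print(fit)
#> 3D residual refinement segmentation network
#>
#> <segnet> 4 modalities -> 5 classes
#>   encoder widths: 8/16/32/64, refine width: 16
#>   backbone 3x3x3 convolutions: 17; trainable parameters: 681,525
#>   curriculum: 3 stage(s) — original -> augment50 -> focal_augment75
#>   final epoch mean loss per stage: 0.6069, 0.3314, 0.02285

pred <- predict(fit, phantoms[[1]]$volume, subvolume_depth = 8)
tab <- evaluate_segmentation(list(pred), list(phantoms[[1]]$labels),
                             scheme = "brats")
print(tab[tab$case == "mean", ], row.names = FALSE, digits = 3)
#>  case    region  dice sensitivity specificity precision
#>  mean     whole 0.990       0.982       1.000     0.997
#>  mean      core 0.981       0.999       0.999     0.963
#>  mean enhancing 0.934       0.890       1.000     0.983
```

The printed block confirms the architecture (17 backbone convolutions; the
desk widths shrink the parameter count from ~12 M to ~0.7 M) and shows the
per-stage loss trajectory; the table reports Dice/sensitivity/specificity/
precision for the nested *whole*/*core*/*enhancing* tumor regions of the
segmented phantom — on these intensity-separable phantoms the trained model
recovers the lesion almost exactly (runtime ≈ 1 minute on one CPU).

The full-scale configuration is `seg_config()` (`describe_network()` prints
the layer table and the 11,976,709-parameter total), and
`plan_windows(155, 12)` / `plan_windows(155, 31)` reproduce the 13-patch
training and 5-sub-volume inference windowing of 155-slice scans. A thin
command-line front end (`inst/cli/brainseg`) exposes `describe`, `phantom`,
`train`, `predict` and `evaluate` subcommands over the same functions.

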