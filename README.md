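# patchpyramid

Coarse-to-fine 3D segmentation of CT volumes with a **hierarchical stack of
patch-based U-Nets**, plus a synthetic CT phantom generator and a
surface-distance evaluation suite — all in R, with the numerical kernels in
compiled code.

## The problem and the model

Clinical CT segmentation has to resolve structures spanning four orders of
magnitude in volume: a mandible is decimetres across, a mental foramen a few
millimetres. A single fixed-resolution network sees either too little
context or too little detail. This package implements a nested-patch
multiscale design:

- Every patch has a **fixed matrix size** M³ (default 32³) but a
  **decreasing physical size**: the coarsest patch spans 80% of the image,
  the finest has 1 mm isotropic voxels, and the D = 4 intermediate spacings
  are exponentially interpolated,
  `s_i = s_0 (s_{D-1}/s_0)^(i/(D-1))`.
- Instead of intensity normalisation, a **channel-splitting layer** expands
  each Hounsfield value into 11 triangular window channels (air, lung, fat,
  soft tissue, bone…), mirroring radiological windowing; the channels form
  a partition of unity.
- Each scale runs a small **U-Net** (feature widths 8, 16, 16, 32, 64;
  max-pooling encoder, transposed-convolution decoder) with `n + 8` output
  channels: `n` label logits (background first) plus 8 free "carry"
  channels. All `n + 8` **logits are forwarded** — centre-cropped and
  trilinearly upsampled — as extra input channels to the next-finer scale,
  so fine networks inherit coarse context.
- Training uses Adam (rate 0.001), label-biased patch sampling (≈80% of
  finest patches contain foreground), joint augmentation (rotation ≤ 10°,
  horizontal flip, scaling ≤ 20%), softmax + categorical cross-entropy for
  volumetrically large labels and a **top-K binary cross-entropy** for
  small ones (per label, only the K highest-loss voxels are averaged).
- Inference descends the pyramid: the coarsest level is tiled everywhere,
  each *promising* patch (max foreground probability ≥ 0.5) spawns child
  patches at probability-weighted random positions, and overlapping
  finest-level predictions are fused by centre-weighted averaging.
- Agreement is quantified per label by **DSC**, **surface DSC** (1 mm
  tolerance), **95th-percentile Hausdorff distance** and **ASSD**, backed
  by an exact Euclidean distance transform and validated against
  exhaustive brute-force oracles.

Because real head-CT data cannot ship with a package, a **phantom
generator** emulates the relevant structure taxonomy on synthetic volumes:
a bone shell, a thin bony plate, an air cavity, a millimetric soft-tissue
canal through the bone wall, a foramen-sized blob in the wall, and a
soft-tissue ellipsoid — each with tissue-plausible HU and additive noise.

## Worked example

```r
library(patchpyramid)

# a phantom "head": volume + 6-label ground truth on a 1 mm grid
spec <- default_cmf_spec(grid_shape = c(96, 96, 96), seed = 1)
ph <- generate_phantom(spec)
ph$volume
#> <pp_volume> 96x96x96 voxels, spacing 1, 1, 1 mm, origin 0, 0, 0 mm, HU range [-1119, 1307]

# pyramid geometry for a 200 mm image with defaults (D = 4, M = 32, 80%)
round(compute_scales(scale_pyramid_spec(), c(200, 200, 200)), 3)
#> [1] 5.000 2.924 1.710 1.000

# train a depth-2 toy stack and predict a held-out phantom
cfg <- train_config(patch_budget = 2000, batch_size = 8, seed = 7,
                    small = small_flags(spec))
pyr <- scale_pyramid_spec(depth = 2, matrix = 16)
train <- lapply(1:20, function(i)
  generate_phantom(default_cmf_spec(seed = 100 + i)))
model <- train_stack(train, cfg, pyr)

held_out <- generate_phantom(default_cmf_spec(seed = 901))
pred <- predict_volume(model, held_out$volume, inference_config(seed = 2))
evaluate_segmentation(pred$labels, held_out$labels)
#>   label   dsc surface_dsc hd95_mm assd_mm ...   (per-label agreement table)
```

The same pipeline is scriptable from a shell via the bundled CLI
(`inst/cli/patchpyramid`): `make-phantom`, `train`, `predict`, `evaluate`,
each writing a resolved-configuration YAML next to its outputs.

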