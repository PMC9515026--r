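---
title: "Hierarchical patch-pyramid segmentation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical patch-pyramid segmentation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The segmentation model

`patchpyramid` segments 3D CT volumes with a stack of small U-Nets
operating on *nested patches*: cubic patches that share one physical centre
and one voxel matrix M³ but shrink in physical size from a coarsest level
spanning a stated fraction of the image down to a finest level at the
working resolution. For a pyramid of depth D with finest spacing
$s_{D-1}$ and coarsest spacing $s_0 = \mathrm{coverage} \cdot
\min(\mathrm{extent})/M$, the intermediate spacings interpolate
geometrically,

$$ s_i = s_0\,\left(\frac{s_{D-1}}{s_0}\right)^{i/(D-1)}, $$

so each level refines resolution by a constant factor. The coarsest patch
supplies anatomical context ("where in the head am I?"), the finest
supplies detail; the levels are tied together by **logit forwarding**: all
$n+8$ output channels of level $i$ — $n$ label logits plus 8 unconstrained
carry channels — are resampled onto level $i{+}1$'s grid (central crop in
the co-centred case, trilinear, applied to raw logits) and concatenated
with its image channels. The carry channels receive no loss and no
activation; they are free context the optimiser can use.

Channel splitting replaces intensity normalisation: each HU value is
expanded into 11 triangular window responses with centres at
−1024, −600, −200, −60, 0, 60, 150, 400, 1000, 1800 and 3071 HU, denser in
the diagnostic soft-tissue range. The windows form a partition of unity
(they sum to 1 for every HU in the domain, verified to 1e−9 in the tests),
are continuous in HU, and values outside the domain are clamped. The
shape of the windows (soft triangular rather than hard rectangular) is this
package's choice: it keeps the mapping continuous and leaves the aggregate
intensity recoverable.

### Per-scale U-Net

Each level runs an independent U-Net with encoder feature widths
(8, 16, 16, 32, 64), two 3³ convolutions per stage, 2³ max-pooling between
encoder stages, 2³ transposed convolutions in the decoder, skip
connections at matching depths, and a linear 1³ output convolution. Two
choices here were genuinely open and are worth recording:

- **Scale-only (RMS) normalisation** follows every hidden convolution:
  activations are divided by their per-channel, per-patch root mean square
  (learned scale γ and offset β; the convolution bias is dropped as
  redundant). The input to the first convolution is a near-one-hot window
  code, not a normalised intensity; without any normalisation, activation
  magnitudes collapse through depth and training stalls. Full instance
  normalisation is the convention in 3D medical segmentation, but its
  mean-centering maps a patch lying wholly inside one tissue to the same
  (zero) features as any other uniform patch — with a 16³–32³ matrix and
  near-uniform patch content this erases exactly the absolute
  window-identity signal the channel-split input carries, and measurably
  stalled class discrimination. Dividing by the RMS controls magnitudes
  while preserving that signal.
- **The classifier head is initialised near zero** (weights ~ N(0, 0.01²)),
  so class probabilities start essentially uniform and early optimisation
  is driven by the data rather than by undoing a random initial labelling.
  An exactly-zero head makes all label logits 0 and softmax probabilities
  exactly uniform — a property the tests exercise explicitly.

### Losses

Labels are designated *large* or *small* per label group. Large labels and
the background form one softmax set trained with mean categorical
cross-entropy over all M³ voxels of every level (levels weighted equally;
coarser levels compare against nearest-neighbour-resampled label patches).
Small labels get an independent sigmoid channel trained with a **top-K
binary cross-entropy**: per label and patch, the per-voxel BCE values are
sorted and only the K largest are averaged. K defaults to 5% of the patch
volume (1638 for M = 32; the originating description gives no K). Voxels
of small labels count as background in the categorical term. Ties at the
K-th position are broken by a stable sort, so the selection is
deterministic and permutation-invariant.

The designation itself is an explicit flag in the training config; when
unspecified, a heuristic flags a label small if its mean foreground
fraction per volume is below 1e−4.

### Training

Adam at learning rate 0.001 (β₁ = 0.9, β₂ = 0.999, ε = 1e−8), batches of 8
patch stacks, and a *patch budget*: one stack of depth D consumes D
patches, and training runs until the budget is spent. Patch centres are
label-biased — a fraction (default 0.8) of centres is guaranteed to hit
foreground — and one augmentation transform (scaling up to 20%, rotation
up to 10° about a uniformly random axis, then a left–right flip with
probability 1/2) is drawn per stack and shared between all levels and the
paired label stack, because per-level transforms would break the nesting
semantics. Rotation is axis-angle (whether the original uses per-axis
Euler angles is unknowable from the description); flips apply after
rotation.

For the biased share of centres, the default sampler first draws a *label*
uniformly among those present, then a voxel of that label, then jitters
within one finest-patch half-extent. Drawing foreground *voxels* uniformly
(available as `balance = "voxel"`) gives a millimetric structure of ~10
voxels essentially zero sampling mass among ~10⁵ foreground voxels;
balancing across labels is what makes small structures appear in the
training stream at all, which matches the stated role of balanced sampling
in the method this package implements.

### Inference

The coarsest level is tiled to cover the volume. A patch is *promising* if
its own predicted maximum foreground probability (softmax for large
labels, sigmoid for small) reaches a threshold (default 0.5) anywhere.
Each promising patch spawns `branching` (default 3) children at the next
level, centred at foreground-probability-weighted random voxels of the
parent — restricted to regions not yet covered at the finest level.
Descent rounds repeat until the coarse level's probable-foreground region
is fully covered by finest patches or a per-level patch cap is reached;
this coverage-driven repetition is this package's resolution of how a
branching factor of 3 can cover a whole volume. Finest-level class
probabilities are fused by weighted averaging with a separable triangular
centre-weight profile (weight 1 at the patch centre, 1/M at the border);
finest patch centres are snapped so patch voxels coincide with volume
voxels. Voxels never visited at the finest level are background. An
exhaustive-tiling mode replaces the random descent with deterministic
tiling of every level; its output is seed-independent and serves as a
regression reference.

With several label groups (each its own trained stack), groups are
predicted independently and merged by an argmax over all groups' label
probabilities against a shared background defined as one minus the maximal
foreground probability; ties go to the lowest label id. Within a single
group the label is the plain argmax over background and every label's
probability — softmax values for large labels, sigmoid values for small
ones. The two families are not on a common scale, but the argmax is the
right comparison: a millimetric canal with sigmoid 0.46 against a bone
softmax of 0.34 should be (and is) assigned to the canal, which a
fixed sigmoid threshold of 0.5 would wrongly suppress.

## Evaluation metrics

Per label: DSC; surface DSC at tolerance τ (default 1 mm — one voxel at
the working resolution); the 95th-percentile Hausdorff distance; and ASSD.
Surfaces are foreground voxels with a face-adjacent background neighbour
(6-connectivity, outside-grid = background); distances are Euclidean
millimetres between surface voxel centres under anisotropic spacing,
computed by an exact two-pass lower-envelope distance transform. Surface
DSC is the mean of the two directed within-tolerance fractions; hd95 pools
both directed distance sets before taking the percentile (one of several
conventions in circulation — declared here, configurable in principle via
the percentile argument); ASSD averages the pooled distances. Empty masks:
DSC is 1 if both masks are empty and 0 if exactly one is; distance metrics
return `NA` with a warning, and `evaluate_segmentation()` reports them as
sentinels. All four metrics are verified against exhaustive brute-force
oracles (pairwise surface distances) on random mask pairs at mixed
spacings, to 1e−9 mm for distances and 1e−12 for ratios.

## The phantom generator

`default_cmf_spec()` emulates the structure taxonomy of a head CT at desk
scale, with six labels: (1) an ellipsoidal high-attenuation shell
(700–1300 HU, diameter 60–80% of the grid, wall 5–8 mm at the 96 mm
reference grid) standing in for the cranial bone; (2) a thin bony plate
(1–2 mm) inside it, a septum analog; (3) an air cavity (−1000 to −950 HU)
in the shell interior, a sinus analog; (4) a 2–4 mm soft-tissue tube
*through the bone wall*, a canal analog; (5) a 2–3 mm blob *in the wall*,
a foramen analog; (6) a soft-tissue ellipsoid (0–80 HU). Canals and
foramina are placed intra-osseously because that is where their anatomical
counterparts live — and because the bone-against-soft-tissue contrast is
precisely what makes millimetric structures segmentable. The canal and
foramen calibres are absolute (they are millimetric by definition);
interior-structure sizes scale with the grid so phantoms remain placeable
at smaller grids. Tube and blob carry the small-label flag.

Geometry is resolved first (shells before structures placed relative to
them), then rasterised in blueprint list order with first-label-wins
precedence; small structures are listed before the shell so they carve the
wall. Intensities are a per-instance mean drawn from the blueprint's HU
range plus i.i.d. Gaussian noise (default σ = 20 HU, a typical soft-kernel
reconstruction noise), rounded to integers. Generation is deterministic
given the spec seed.

What the phantom does **not** emulate: beam hardening, scatter, partial
volume beyond grid discretisation, anatomical shape variability,
pathology, and inter-observer labelling noise. Tests passing on phantoms
therefore demonstrate that the pipeline's machinery is correct and
trainable, not that clinical-grade accuracy transfers to real scans.

## Numerical and convention choices

- Voxel model: node-centred; voxel (i,j,k) (1-based) sits at
  `origin + (i-1)·spacing`; extent = shape × spacing. One convention
  everywhere removes off-by-half ambiguity; a half-voxel mismatch between
  patch sampling and fusion is exactly the class of bug the oracle
  inference test (`DSC = 1` for every label, including a 5-voxel foramen)
  pins down.
- Out-of-bounds reads: −1024 HU (air) for volumes, 0 (background) for
  labels, 0 for forwarded logits.
- Resampling: trilinear for intensities, nearest-neighbour for labels —
  label values are never invented.
- Oblique NIfTI orientations are normalised to axis-aligned at load with a
  warning; the pipeline assumes axis-aligned grids.
- Instance-norm ε = 1e−5; stable softmax (max subtraction) and
  log1p/pmax-based BCE throughout.
- All randomness flows through explicit seeds fanned out into per-purpose
  substreams (initialisation, sampling, augmentation, descent), and
  library code saves/restores the caller's RNG state.

## Problem sizes used in the tests

The test suite trains a depth-2, M = 16 toy stack on twenty 96³ phantoms
with a 2000-patch budget and evaluates five held-out phantoms; gradient
correctness is checked by finite differences on miniature networks
(features (2, 3), M = 4); metric oracles run on 24³ grids; oracle-driven
inference runs on 64³ phantoms. These sizes were chosen so the full suite
exercises every pathway of the real pipeline — sampling, augmentation,
batched forward/backward, descent, fusion, metrics — on a single CPU in
minutes; the defaults (D = 4, M = 32, 2 × 10⁶ patches) remain available
through the same configuration objects for full-scale runs.

## Known limitations

- Training throughput is CPU-bound (hand-rolled conv kernels over BLAS);
  the 2-million-patch full-scale regime is supported by configuration but
  is a multi-day CPU computation.
- Optimisation at Adam 0.001 from random initialisation needs on the order
  of 10²–10³ steps before class posteriors become confident; very small
  patch budgets produce under-trained models whose coarse level may not
  pass the promising threshold anywhere (the prediction is then empty, by
  design). Volumetrically tiny labels (a ~10-voxel foramen analog) are the
  slowest to emerge under the top-K regime and need the largest budgets.
- No mixed precision, no multi-device parallelism, no test-time
  augmentation, no learned window parameters.
- The fusion rule, the promising criterion, the hd95 pooling convention
  and the multi-group merge are declared conventions, not derived facts;
  all are localised behind small functions if a different convention is
  needed.
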