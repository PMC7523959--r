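---
title: "Nucleus-aware instance segmentation by feature pyramid fusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleus-aware instance segmentation by feature pyramid fusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fpfuse)
```

## The problem

Macrophages in two-channel fluorescence microscopy (a DNA stain marking
nuclei, a cytoplasm stain marking cell bodies) are hard to segment as
*instances*: the cells are morphologically complex, they adhere in clusters,
and the cytoplasm signal changes only faintly where two cells touch. A
nucleus, by contrast, is round, bright, and nearly always one-per-cell — so
nucleus information is the natural key for splitting a clump of cytoplasm
into individual cells. `fpfuse` implements a two-stage region-proposal
detector (in the Mask R-CNN family) whose cell branch is *fused*, level by
level, with the feature pyramid of a previously trained and frozen nucleus
detector.

## Model

### Backbone

The feature extractor is a reduced ResNet-50: a 7×7, 64-filter, stride-2
stem with 3×3 max pooling, followed by four bottleneck stages with inner
widths (32, 64, 128, 256) — half the standard widths — and block counts
(2, 2, 3, 2) — roughly half the standard (3, 4, 6, 3). Stage outputs C2..C5
have strides 4–32 and 128–1024 channels; for a 224×224 input the spatial
sizes are 56, 28, 14, 7. `width_multiplier` scales all stage widths
(0.5 is the reduced architecture, 1 the original; micro experiments use
0.25).

One number worth recording: an exact layer-by-layer tally gives 23.51M
parameters for the original backbone and 3.78M for the reduced one — a
ratio of 6.22, not the "about ten times" sometimes quoted for this kind of
halving. Halving widths divides convolution parameters by four, but halving
block counts removes less than half of the parameters because the remaining
blocks include all the projection shortcuts, so the true factor is ~6.

Batch normalization runs with frozen statistics (a trainable per-channel
scale and shift). This is the standard choice for detection fine-tuning at
batch size 1, where batch statistics are meaningless. Because no
normalization of activations takes place, the final BN scale of every
bottleneck block is initialized at zero so each block starts as an identity
mapping and the activation variance stays bounded at depth; all other
convolutions are He-initialized, and the objectness/regression/mask score
layers start with small weights (σ = 0.01) so initial losses sit at their
chance values.

### Feature pyramid and fusion

A standard top-down feature pyramid is built on C2..C5: 1×1 lateral
projections to a common `pyramid_width` (default 256), nearest-neighbour
2× upsampling with addition, a 3×3 smoothing convolution per level, and P6
as a stride-2 subsample of P5 (strides 4, 8, 16, 32, 64).

Three variants are available:

* **cell_only** — a single-channel detector on the cytoplasm stain (the
  same architecture, applied to the nucleus stain, is the stage-1 nucleus
  model);
* **early_fusion** — the nucleus image enters as a second input channel.
  `adapt_first_layer_two_channels()` duplicates and halves a 1-channel stem
  kernel so that identical inputs on both channels reproduce the original
  activations exactly;
* **fpf** — feature pyramid fusion: a frozen nucleus branch (backbone +
  pyramid, seeded from a stage-1 nucleus model) is merged into the cell
  pyramid per level, either by element-wise addition (channel count
  unchanged) or by concatenation (doubled). For concatenation a trainable
  1×1 projection restores `pyramid_width` by default so downstream heads
  are merge-mode invariant; it can be disabled (`concat_projection =
  FALSE`). Fusion is applied to the final per-level pyramid outputs (after
  the 3×3 smoothing), the most conservative reading of "fused with features
  of the feature pyramid".

Freezing is structural, not cosmetic: nucleus-branch parameters are marked
as not requiring gradients, the reverse-mode sweep prunes the whole branch,
and the optimizer never touches them — so they are bit-identical before and
after any number of cell-training steps.

### Detection heads

A region proposal network (3×3 conv + 1×1 objectness and box-delta heads)
runs on every pyramid level with one anchor scale per level (32, 64, 128,
256, 512 px) and aspect ratios (0.5, 1, 2) — the reference defaults, since
anchor optimization is explicitly left open by the method. Proposals are
decoded with the standard (dx, dy, log dw, log dh) box coding, clipped,
filtered, and reduced by greedy NMS at IoU 0.7.

Boxes are routed to pyramid levels with the standard FPN heuristic
k = ⌊4 + log2(√(wh)/224)⌋ clamped to 2..5. RoI-Align extracts 7×7 crops for
the box head (two fc layers, class logits and box deltas) and 14×14 crops
for the mask head (3×3 convolutions, a 2× nearest upsample + 3×3 conv, and
a 1×1 logit layer → 28×28 mask logits). RoI-Align averages bilinear samples
on a regular grid inside each bin, with pixel centres at half-integer
continuous coordinates — no quantization; constants are reproduced exactly
and linear ramps are interpolated to machine precision (both are tested).

### Loss

The multi-task loss is

L = L_rpn_cls + 2·L_rpn_box + L_cls + 2·L_box + 2·L_mask,

with cross-entropy classification terms, smooth-L1 box regressions, and a
per-pixel sigmoid binary cross-entropy on the 28×28 mask crops. Both
regression losses and the mask loss carry the factor-2 weighting. When a
model is built with `weighted_loss = TRUE`, the mask term is multiplied
pixel-wise by the border weight map crop (below).

### Border-weighted mask loss

Cell borders — especially the faint contact lines inside clusters — are the
hard pixels. `contour_weight_map()` extracts 1-px instance contours
(4-adjacency to a different label, image borders counting as background),
convolves them with an isotropic Gaussian (25×25 kernel, σ = 5, zero
padding), and maps the field affinely so weights lie in [1, 2], with 2 on
contours and 1 beyond kernel reach.

A normalization subtlety: normalizing by the *image-wise* peak of the
blurred field makes weights non-monotone — drawing an extra cell elsewhere
could lower the weights of an existing border. We therefore normalize by
the kernel's own peak G(0,0) and clip at `max_weight`. An isolated contour
pixel then gets weight exactly 2 at itself and 1 + e^(−1/2) ≈ 1.607 at
distance 5 (the closed forms the tests pin down), dense contour ridges
saturate at 2, and adding contour pixels never decreases any weight.
`crop_weights()` resizes the boxed region of the map to the 28×28 mask-loss
grid bilinearly.

## Training

Momentum SGD (lr 0.001, momentum 0.9, weight decay 0.0001 on convolution
and fc weights) in three phases: heads + RPN + pyramid for 100,000
iterations; everything deeper than conv4 (stages conv4_x and conv5_x) joins
for 250,000; the whole network trains for 500,000 more at lr 0.0001. A
single `scale` factor shrinks all three budgets jointly for desk-size runs
(1/1000 gives 100 + 250 + 500 = 850 iterations). Augmentation is random
crops (with reflect padding when the frame is smaller than the crop),
horizontal/vertical flips and 90° rotations, applied consistently to
channels, masks and boxes. One image per step, one worker; a fixed seed
makes training bit-reproducible.

During training, ground-truth boxes are appended to the RPN proposals
before RoI sampling (512 RoIs at a 1:3 positive ratio by default) so the
heads see positives while the RPN is still warming up — the standard
Mask R-CNN recipe.

The ImageNet-grayscale classification pretraining of the original recipe
is out of scope here (it needs 1.2M external images); backbones start from
He initialization. This mainly costs sample efficiency, which the synthetic
experiments absorb by overfitting small scene sets.

## Ground-truth bootstrapping

`bootstrap_ground_truth()` reproduces the two-step initial annotation:
(1) threshold segmentation per channel (Otsu by default, fixed threshold
for noiseless data) with morphological closing and a minimum-area filter —
the unspecified "contour processing" is kept minimal on purpose; (2) every
cell containing more than one nucleus is split by assigning each cell pixel
to the nearest nucleus in Euclidean distance. Distance is measured to the
nucleus *mask* (a distance transform), not its centroid, which is robust
for elongated nuclei; ties go to the lower nucleus label for determinism.
The split is an exact partition of the cell mask. The downstream manual
refinement of the original workflow is explicitly not replicated.

On noiseless, non-clustered synthetic scenes the bootstrap recovers the
generator's instances at per-instance IoU ≥ 0.95 — a self-consistency
oracle the tests enforce.

## Rule-based post-processing

Three steps, in order, refine predicted cell instances using nucleus
predictions and a threshold-based foreground map:

1. **merge** — cells overlapping a common nucleus are unioned (transitive
   closure over chains);
2. **recover** — foreground minus predicted masks is closed morphologically
   (3-px disc), components under `min_region_area` (default 40 px, about
   the smallest plausible nucleus at 20×) are dropped, and each remaining
   region is appended to its unique 8-adjacent cell, discarded if adjacent
   to several, or promoted to a new instance if adjacent to none;
3. **expand** — uncovered nucleus pixels are added to the unique overlapping
   cell, or an entirely uncovered nucleus becomes a new cell.

After completion every nucleus pixel is covered by exactly one cell
instance, and applying the pipeline twice changes nothing (idempotence);
both laws are tested on generated fixtures. Mirroring the original
evaluation protocol, post-processing is off by default in comparisons.

## Evaluation protocol

Mask (or box) IoU; per image, the 100 top-scoring detections are greedily
matched in descending score order to the unmatched ground-truth instance of
highest IoU at threshold t; unmatched detections are FP, unmatched truth
FN. Detections of all test images are pooled before the precision/recall
curve is built (per-image AP averaging cannot reproduce a single AP per
threshold). AP(t) is the 101-point interpolated average precision — the
mean over r ∈ {0, 0.01, …, 1} of the maximum precision at recall ≥ r — and
the mean AP averages the nine thresholds 0.50–0.90 (step 0.05). An AP with
zero ground truth is undefined and propagates as missing; `mean_ap()`
errors on missing values unless told to omit them, since published tables
handle such cells ambiguously.

The implementation is checked against a brute-force oracle (explicit prefix
counting and grid scan) on 200 random match configurations to 1e-12, and
against worked examples (a TP at score 0.9 plus an FP at 0.8 over 2 ground
truths gives AP = 51/101).

## Synthetic scenes

The generator emulates the benchmark's statistical challenges rather than
its optics: star-convex cells (an ellipse with low-order harmonic ripple,
axis ratio 0.7–1, ripple amplitude ≤ 0.22) packed into the frame with a
configurable fraction arranged in touching clusters of 2–4; overlap regions
are partitioned by the pixel-wise argmin of normalized radial distance, a
Voronoi-like rule that matches the annotation convention of the emulated
dataset. Each cell carries one round nucleus strictly inside its mask — two
with probability `multinucleate_rate` — and nuclei keep a ≥4 px mutual gap
so they stay separable, as in the real data. Cells may be truncated by the
frame border. Rendering paints constant plateaus (background 0.05, cytoplasm
0.55, nucleus 0.8 on a [0, 1] scale), dims 2-px cell-cell contact bands by
`contact_attenuation` (default 0.3 — "faint" but learnable), and adds
Gaussian noise (σ = 0.02). The defaults (512×512 frames, 12 cells, cluster
fraction 0.5, multinucleate rate 0.05) give densities comparable to the
emulated 20× frames.

What the generator does *not* model: point-spread-function optics, spatial
intensity gradients and vignetting, texture inside cytoplasm, the real
dataset's intensity histograms, and bacterial (GFP) signal. Passing tests
on synthetic scenes therefore demonstrate that the machinery is correct and
trainable, not that the reported real-data accuracies transfer.

All randomness flows from one seed; per-sample streams are derived by a
fixed affine counter, and rendering is a pure function of (truth, config).

## Problem sizes and numerical choices

* Micro experiments (tests, acceptance script) use 5 scenes of 128×128 px
  with 5 cells each, a 0.25-width backbone, pyramid width 128, narrow heads
  (fc 256, mask channels 64), and the schedule scaled by 1/1000 (850
  iterations). Under these conditions the detector overfits its training
  scenes to mask AP@0.5 close to 1 and the total loss falls well below half
  of its early value.
* Degenerate inputs: zero-area boxes route to pyramid level 2; empty ground
  truth zeroes the box/mask losses behind a count guard; an all-background
  image thresholds to an empty instance set; an empty mask pair has IoU 0.
* Box coordinates are 0-based half-open; pixel (r, c) has its centre at
  continuous (c − 0.5, r − 0.5). Mask pasting uses nearest-neighbour
  resizing, so pasted area equals the area of the resized box-space mask.
* Tie-breaks: matching prefers the first (highest-IoU) ground truth;
  nearest-nucleus splitting prefers the lower nucleus label; NMS keeps the
  higher score.
* The decoded box log-scale is capped at log(1000/16) as in reference
  implementations.

## Known limitations

* No GPU path: the engine is CPU-only R/C++ and is meant for method
  development, micro-scale studies and teaching, not 850k-iteration
  training runs on real microscope data.
* The parameter-count ratio of original to reduced backbone is 6.22 by
  exact tally (see above), short of the informal "ten times".
* The nucleus branch at inference is the frozen stage-1 model inside the
  fpf network, so one forward pass yields cell predictions; nucleus
  predictions for post-processing come from running the stage-1 model
  itself.
* Detections are serialized as label-mask TIFFs and tibbles rather than
  run-length-encoded JSON; the evaluation protocol consumes masks directly.
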