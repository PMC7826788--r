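---
title: "Self-attention modules for lung-field segmentation: model, design and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-attention modules for lung-field segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Lung-field segmentation on chest radiographs — one binary mask per image,
ideally two clean connected regions — underpins downstream measurements such
as the cardiothoracic ratio. `lungattn` implements a pair of light-weight
self-attention modules (called X and Y here) that can be inserted at any of
the four resolution stages of a U-Net, together with everything needed to
train and evaluate the resulting network end to end: preprocessing,
post-processing, Dice/sensitivity/PPV scoring, cross-validation machinery,
and a synthetic phantom generator so that the whole pipeline is testable on
a laptop with no clinical data.

All numeric machinery (a small reverse-mode autodiff over dense arrays, with
C++ im2col convolution kernels) lives inside the package; there is no deep
learning framework dependency.

## The attention modules

**Channel attention** answers "what" to attend to. A feature map
$F_{\mathrm{input}} \in \mathbb{R}^{C \times H \times W}$ is collapsed by
global average pooling to one scalar per channel, passed through a
one-hidden-layer MLP, batch-normalized and rectified:

$$F_{\mathrm{channel}} = \mathrm{ReLU}(\mathrm{BN}(W_1\,\sigma_h(W_0\,\mathrm{GAP}(F_{\mathrm{input}}))))
\in \mathbb{R}^{C \times 1 \times 1},$$

with hidden width $\max(1, \lfloor rC \rceil)$ controlled by the reduction
ratio $r$ (default 0.5, i.e. the bottleneck halves the channel count) and
$\sigma_h$ a ReLU. Because pooling precedes everything else, the output is
invariant to any spatial permutation of the input — a property the test
suite checks directly.

**Spatial attention** answers "where". The feature map runs through a
three-scale convolutional pyramid in the spirit of a feature pyramid
network: two stride-2 3×3 convolutions down to scales $H/2$ and $H/4$, one
3×3 convolution at the coarsest scale, then an expanding path with lateral
additions and two more 3×3 convolutions, and finally an addition of the
input map at full scale. Exactly five learnable 3×3 convolution layers,
channel width held at $C$ throughout; up-sampling is parameter-free
(bilinear by default, nearest-neighbour available, and used by the oracle
tests), so the budget stays at five.

**Fusion and residual refinement.** The X-attention map is

$$M_X(F_{\mathrm{input}}) = \sigma(F_{\mathrm{spatial}} \otimes F_{\mathrm{channel}}),$$

each channel plane of the spatial output scaled by its channel weight and
squashed to $(0,1)$. The Y variant takes its channel attention from a
*deeper* feature map $F'_{\mathrm{input}}$ (which carries more global
context, and may have a different channel count — the MLP adjusts it to
$C$), while spatial attention still comes from the shallow map:

$$M_Y(F_{\mathrm{input}}, F'_{\mathrm{input}}) = \sigma(F_{\mathrm{spatial}} \otimes F'_{\mathrm{channel}}).$$

Either map gates its feature map residually,

$$F_{\mathrm{output}} = M \otimes F_{\mathrm{input}} + F_{\mathrm{input}},$$

so the module can only modulate the identity path: for non-negative input,
$F \le F_{\mathrm{output}} \le 2F$ elementwise.

## Network wiring

The segmentation network is a U-Net with a residual encoder: a
full-resolution stem, four stride-2 residual stages (positions 1–4,
position 1 being the shallowest/highest-resolution stage), one further
stride-2 bottom block, and a transposed-convolution decoder that
concatenates each up-sampled decoder feature with the same-stage skip and
applies two 3×3 conv+BN+ReLU layers. Input sizes must be divisible by
$2^5 = 32$. The final layer is a 1×1 convolution with a sigmoid, matching
MSE training against binary masks.

- `X(i)` refines the stage-*i* encoder output before it enters both the
  skip connection and the next stage.
- `Y(i)` sits on the decoder: its shallow input is the stage-*i* skip
  (already X-refined if `X(i)` is present, which realizes the X→Y
  chaining), and its deep input is the decoder feature arriving from the
  next-deeper stage. The Y-refined skip is then concatenated as usual.

Design choices that the source material left open, fixed here once:

- **Pyramid instantiation.** Scale count and downsampling mechanism are
  unspecified; we use 3 scales with stride-2 3×3 convolutions, which is the
  unique instantiation consistent with a five-3×3-layer budget of the form
  2 contracting + 1 coarsest + 2 expanding.
- **Reduction ratio semantics.** The stated ratio 0.5 is read
  SENet-style as `hidden = max(1, round(r * C))` (hidden = C/2), not as a
  literal division by `r` (which would double the width).
- **"Added together".** The expanding-path output is added to the raw
  input map before returning, which preserves exact identity behaviour
  under zero kernels — a property the tests pin down.
- **Position numbering.** Position 1 = shallowest stage, consistent with
  attention at "lower layers" helping local detail.
- **Y deep input.** The next-deeper decoder feature (it aggregates global
  context); alternative wirings are not configurable.
- **Batch norm at tiny batches.** Running statistics are used at batch
  size 1 and in evaluation mode; training batches of ≥ 2 use batch
  statistics (momentum 0.1 on the running estimates).
- **Initialization.** Fan-in-scaled uniform weights with a caller-provided
  seed; biases zero; batch-norm scale 1, shift 0.

A ResNet-101-style encoder preset (bottleneck blocks, 3/4/23/3 per stage,
widths 256–2048) exists for parameter accounting and scale studies; the
default `tiny` preset (widths 8/16/32/64, one basic residual block per
stage) is what every test trains, because it fits a single CPU. On the
parameter budget: one Y module is five 3×3 convolutions at width $C$ plus a
small MLP, i.e. about $45C^2$ learnable scalars. Against the
ResNet-101-style baseline (≈ 230M parameters) that is below 1% for
$C \le 128$ but ≈ 1.4% at $C = 256$; the "five filters" structural claim
is exact at every width and is what the acceptance checks assert.

## Pre- and post-processing

Images are resized (bilinear) to the network size and then histogram
equalized — equalization after resizing so its statistics match the
resolution the network sees. Equalization is the global 256-bin CDF remap
`round(255 * cdf(v))`; it is monotone, and a constant image maps to 255. No
mean/std normalization is applied; the 8-bit image is only scaled by 1/255
on entry to the network.

Predictions are binarized at 0.5 — the decision boundary of an MSE fit to
{0,1} targets, with strict inequality so an exactly-0.5 map is background —
and all but the two largest connected components are removed
(8-connectivity by default so diagonal border pixels merge; ties between
equal areas are broken toward the component whose first pixel comes
earliest in row-major order, making the operation deterministic). The
filter never adds a pixel and is idempotent.

Dice, sensitivity and PPV come from exact pixel confusion counts. With an
empty truth *and* empty prediction all three are 1 by convention; a metric
whose own denominator is 0 otherwise scores 0. Test-set results are
macro-averaged (per-image metrics, equal weights); pooled-pixel averaging
is available as an option. Cross-validation folds are aggregated as
arithmetic mean ± sample standard deviation (n−1), formatted to three
decimals.

## Training regimen

`train_config()` defaults encode the reference regimen: mini-batch 4,
SGD (momentum 0.9, no weight decay), initial learning rate 0.01 divided by
10 whenever the best validation Dice has not strictly improved for 5
consecutive evaluations (counter resets on decay), early stopping after 15
stale evaluations, MSE loss between the sigmoid map and the binary mask, at
most 10,000 iterations (optimizer steps), reduction ratio 0.5, and no data
augmentation. "Validation accuracy" is read as validation Dice — the only
quality metric reported — computed with the full binarize + two-components
post-processing. The best-Dice checkpoint is kept; checkpoints are single
JSON files with base64-encoded double-precision payloads, so
save → load → predict round-trips bitwise.

Patience values (5 plateau / 15 early-stop evaluations, evaluation every 50
iterations) are package defaults where the source regimen is silent, and
are configurable.

## The phantom generator

`generate_phantom()` draws two star-shaped lobes — ellipses with a smooth
low-order harmonic perturbation of the radius, so each lobe is one
connected component by construction — placed disjointly in the left and
right half of the frame. Per-lobe area fractions are sampled from
[0.08, 0.22], keeping the total lung fraction within [0.15, 0.45];
eccentricities from [1.4, 2.2] make lobes taller than wide. The image
renders lungs dark (level ≈ 80) on brighter tissue (≈ 170), matching
radiograph polarity (a `polarity` flag inverts this), plus a smooth
background field, periodic rib-like stripes (amplitude 12 gray levels,
period ≈ H/7), and Gaussian pixel noise (sd 8) clipped to 8 bits.
Generation is a deterministic function of the spec, including its seed.

The phantoms reproduce exactly the structural assumptions the pipeline
relies on — two disjoint single-component lung fields, boundary noise, a
textured background — and nothing else: no pathology (effusions,
pneumothorax, nodules), no anatomy outside the lungs, no X-ray physics, no
inter-patient variability in pose or exposure. Passing the phantom-based
tests therefore demonstrates that the machinery is correct and that the
network can learn this family of shapes; it says nothing about clinical
performance, which in the source experiments required the real Montgomery,
JSRT and Shenzhen datasets and GPU-scale training.

## Problem sizes used by the test suite

The suite trains the `tiny` encoder at 64×64: an overfit check (8 phantoms,
300 iterations, training Dice ≥ 0.95 after post-processing) and a
scaled-down ablation (20 phantoms, 2 folds, 40 iterations per fold over
{baseline, X(1), Y(1), X(1)+X(2)+Y(1)+Y(2)}) whose purpose is the
integrity and formatting of the mean ± sd table, not the ranking of
configurations — at this scale differences between placements are noise.
`scripts/acceptance.R` additionally trains one 70/10/20 cross-validation
fold of a 20-phantom dataset (300 iterations) and reports held-out Dice,
sensitivity and PPV. Equation-level operations are pinned against
independent nested-loop oracles at ≤ 16×16 within 1e−6, and gradients
against central finite differences.

## Known limitations

- CPU-only and desk-scale by design; the ResNet-101 preset is buildable
  but not trainable in reasonable time without hardware acceleration, and
  ImageNet pre-training is only a weight-loading hook
  (`load_checkpoint()` accepts externally produced checkpoints).
- Single foreground class (lungs); no hearts or clavicles.
- The interplay between a single 70/10/20 split and five-fold
  cross-validation in the reference protocol is ambiguous; `make_splits()`
  reconciles them as five rotating disjoint 20% test folds with a 70/10
  train/validation division of the remainder, which keeps both stated
  properties (the per-fold proportions and the exhaustive disjoint test
  partition).
- MSE on a sigmoid output trains noticeably slower than cross-entropy for
  heavily imbalanced masks; it is kept because it is part of the reference
  regimen.
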