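# lungattn

Self-attention augmented U-Net for lung-field segmentation in chest
radiographs — with everything needed to train, evaluate and stress-test the
pipeline on synthetic lung phantoms, on a single CPU, with no deep-learning
framework.

## What it does

Segmenting the two lung fields in a chest X-ray is a prerequisite for
downstream measurements (e.g. the cardiothoracic ratio). This package
implements two light-weight self-attention modules and the segmentation
network built around them:

- **Channel attention** (squeeze-and-excitation style): a feature map
  `F ∈ R^{C×H×W}` is compressed by global average pooling and passed
  through a one-hidden-layer MLP with reduction ratio r = 0.5, batch
  normalization and ReLU, giving one non-negative weight per channel —
  *what* to attend to.
- **Spatial attention**: a three-scale convolutional pyramid (exactly five
  learnable 3×3 convolution layers: two stride-2 contracting, one at the
  coarsest scale, two expanding with lateral additions), added back to the
  input map — *where* to attend to.
- **X-attention map** `M_X(F) = σ(F_spatial ⊗ F_channel)`, both attentions
  from the same feature map; **Y-attention map**
  `M_Y(F, F′) = σ(F_spatial ⊗ F′_channel)`, the channel weights taken from
  a *deeper* feature map `F′` that carries global context (its channel
  count is adjusted by the MLP). Either map gates its feature map
  residually: `F_out = M ⊗ F + F`, so for non-negative input
  `F ≤ F_out ≤ 2F`.
- A **U-Net with a residual encoder** (four stride-2 stages below a stem,
  transposed-convolution decoder) where X modules can refine any encoder
  stage 1–4 and Y modules any decoder stage; placing `X(i)` and `Y(i)`
  together chains them, since the X-refined skip is what Y receives.
  Placements are parsed from labels such as `"X(1)+X(2)+Y(1)+Y(2)"`.
- The full experimental protocol: resize + global histogram equalization,
  binarization at 0.5, keep-two-largest-components post-processing,
  Dice / sensitivity / PPV from exact pixel confusion counts, 70/10/20
  splits with five disjoint rotating test folds, SGD (batch 4, lr 0.01,
  MSE loss) with plateau ÷10 learning-rate decay and early stopping, and a
  cross-validated ablation runner over attention placements.
- A **phantom generator**: paired image/mask sets of two star-shaped lung
  lobes (dark on brighter tissue, rib-like stripes, boundary and pixel
  noise), so the entire pipeline is testable without clinical data.

All numerics — including a small reverse-mode autodiff with C++ im2col
convolution kernels — live in the package. See the vignette
(`vignettes/attention-unet.Rmd`) for the model, every design decision, and
what phantom-based validation does and does not show.

## Worked example

Attention maps and residual gating on a toy feature map:

```r
library(lungattn)
set.seed(1)
f  <- array(rnorm(8 * 16 * 16), c(8, 16, 16))       # C x H x W
cp <- channel_attention_params(8, seed = 1)
sp <- spatial_attention_params(8, seed = 2)
m  <- x_attention_map(f, cp, sp)
range(m)
#> attention map range: 0.3545 0.7535      (always strictly inside (0, 1))
```

Train the best-performing placement on eight 64×64 phantoms and score the
training set (the desk-scale overfit check; ~2 minutes on one CPU):

```r
generate_dataset(8, base_seed = 1, out_dir = "phantoms", size = 64)
manifest <- read_manifest("phantoms/manifest.csv")
spec <- network_spec("tiny", input_size = 64,
                     placement = "X(1)+X(2)+Y(1)+Y(2)")
net  <- build_network(spec, seed = 2)
cfg  <- train_config(max_iterations = 300, eval_interval = 50, seed = 3)
fit  <- train_network(net, manifest,
                      list(train = manifest$id, validation = manifest$id), cfg)
ev   <- evaluate_network(fit$checkpoint, manifest)
ev$mean
#>        dice sensitivity         ppv
#>   0.9687255   0.9665949   0.9714813
```

Each prediction is binarized at 0.5 and reduced to its two largest
connected components before scoring, so the Dice of 0.969 means the
network recovered the two phantom lung fields almost pixel-perfectly after
150 passes over eight images. Fold aggregation formats results the
standard way:

```r
aggregate_metrics(list(list(dice = 1,    sensitivity = 1,    ppv = 1),
                       list(dice = 0.96, sensitivity = 0.95, ppv = 0.97),
                       list(dice = 0.98, sensitivity = 0.97, ppv = 0.99)))
#>        metric      mean         sd     formatted
#> 1        dice 0.9800000 0.02000000 0.980 ± 0.020
#> 2 sensitivity 0.9733333 0.02516611 0.973 ± 0.025
#> 3         ppv 0.9866667 0.01527525 0.987 ± 0.015
```

A thin command-line front end with `synth`, `train`, `evaluate` and
`ablate` subcommands is installed at `inst/cli/lungattn`.

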