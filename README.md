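# octfusion

Dual-branch CNN–transformer classification of retinal OCT B-scans, in R.

Optical coherence tomography (OCT) is the workhorse imaging modality for
retinal disease (CNV, DME, drusen, AMD, ...). Convolutional networks read
local texture well but miss long-range geometry; vision transformers do the
opposite. `octfusion` implements a hybrid classifier for researchers who
want a fully inspectable, dependency-light R implementation of this model
family: a residual CNN branch and a shifted-window self-attention (Swin
style) branch run side by side, and a per-stage **feature fusion module**
exchanges information between them.

## The model

For an input image $x$, stage $i \in \{1..4\}$ produces CNN features $d_i$
(bottleneck residual blocks, resolution halving, width growing) and token
features $k_i$ (window/shifted-window multi-head self-attention with
cyclic-shift masking and relative-position bias, patch merging between
stages; widths $C, 2C, 4C, 8C$ on grids 56/28/14/7 at 224 px). The fusion
module computes

$$f_i = \mathrm{ICAB}(\mathrm{CRB}([k_i; P(d_i)])) + Q(f_{i-1}),$$

where CRB is channel concatenation followed by a residual 3×3 conv block,
ICAB rescales channels by $\sigma(\mathrm{FC}(\mathrm{GAP}(\cdot)))$, $P$
and $Q$ are 1×1 projections (Q stride-2: the multi-level chain across
stages), and the two channel halves of $f_i$ are projected and added back
into their branches. The stage-4 fused map feeds a GAP → 1024-unit FC →
softmax head. Training uses Adam (decoupled weight decay 0.05, cosine
learning rate $10^{-4}\!\to\!10^{-6}$) with an epoch-scheduled hybrid loss:
focal loss $-\alpha(1-\hat y)^\gamma\log\hat y$ for epochs $t \le n$
($n = 30$), then the bounded correntropy loss
$1-\exp(-(y-\hat y)^2/\sigma^2)$. Evaluation reports per-class one-vs-rest
Acc/Pre/Rec/F1/Spe and macro averages; `grad_cam()` produces class
activation heatmaps.

Because no deep-learning framework exists in this R stack, the package
carries its own reverse-mode autodiff tape (BLAS-backed im2col convolutions
and a fused window-attention op); every backward rule is checked against
finite differences in the test suite, and the shifted-window attention is
checked against a brute-force region-wise oracle.

A deterministic synthetic generator (`synthetic_spec()`,
`generate_dataset()`, `write_imagefolder()`) emulates OCT-like layered
images with class-specific lesion motifs so that the whole pipeline —
dataset scanning, 7:2:1 largest-remainder splitting, training, evaluation,
Grad-CAM — runs end to end with no downloads.

## Worked example

```r
library(octfusion)

# 2-class synthetic dataset: plain banded retina vs bright-blob lesion
spec <- synthetic_spec(num_classes = 2, images_per_class = 24,
                       image_size = 64, noise_sd = 8, seed = 7)
imgs <- generate_dataset(spec)
lab  <- vapply(imgs, `[[`, 0L, "label")
split <- ifelse(ave(seq_along(lab), lab, FUN = seq_along) <= 20, "train", "val")
ids  <- vapply(imgs, `[[`, "", "identifier")
write_imagefolder(imgs, "oct_synth", setNames(split, ids))
index <- scan_imagefolder("oct_synth")

fit <- oct_fit(index, oct_config(2, preset = "tiny"),
               train_config(epochs = 40, batch_size = 8,
                            lr_init = 1e-3, lr_min = 1e-5, seed = 7),
               loss_config(switch_epoch = 30, total_epochs = 40))
print(fit)
#> oct_fit: 40 epochs (correntropy loss at end), 2,794,558 parameters
#>   final train acc 1.000, val acc 0.750; best val loss 0.0002 (epoch 8)
#>   convergence epoch (0.5% adjacent-error rule on val loss): 18
```

The tiny (64-pixel, ~2.8 M parameter) model drives training accuracy to
1.000 within 200 optimisation steps; the loss branch switches from focal to
correntropy after epoch 30, visible in `fit$history$loss_branch`. Metrics
and heatmaps:

```r
evaluate_model(fit, index, split = "val")$report$average
#>    Acc       Pre  Rec        FS  Spe
#> 1 0.75 0.8333333 0.75 0.7333333 0.75

im <- render_image(1, spec, 8)                    # a bright-blob image
h  <- grad_cam(fit, preprocess(im, size = 64), layer = "swin2")
print(h)
#> oct_heatmap: layer swin2, class 1, peak at (28, 36)
round(unlist(im$lesion[c("y", "x", "radius")]), 1) # ground-truth lesion
#>      y      x radius
#>   29.2   35.4    8.0
overlay(h, im, file = "cam.png")                  # heat overlay PNG
```

The heatmap peak (row 28, column 36) falls inside the known lesion box. The same pipeline is
scriptable from a shell via `inst/cli/octfusion`
(`synth` / `train` / `eval` / `gradcam` / `describe` subcommands, YAML or
JSON config).

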