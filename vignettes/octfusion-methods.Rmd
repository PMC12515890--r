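---
title: "Methods: a dual-branch CNN-transformer classifier for retinal OCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a dual-branch CNN-transformer classifier for retinal OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(octfusion)
```

## The model

Retinal OCT B-scans carry two kinds of diagnostic evidence: local texture
(drusen deposits, small cavities, layer discontinuities) and global geometry
(dome-shaped elevations, large-scale layer displacement). `octfusion`
implements a dual-branch classifier that models both:

* a **CNN branch** — a four-stage residual network of bottleneck blocks
  (1×1 reduction, 3×3 spatial convolution, 1×1 expansion, with identity or
  projected skips), two blocks per stage by default, behind a 7×7 stride-2
  stem with 3×3 stride-2 max pooling. Resolution halves per stage while
  width grows.
* a **transformer branch** — hierarchical shifted-window self-attention.
  The image is tokenized into 4×4 patches embedded to width $C$; stages of
  depth (2, 2, 6, 2) alternate window attention (W-MSA) and shifted-window
  attention (SW-MSA, cyclic shift $\lfloor M/2\rfloor$ with the standard
  region mask so attention only joins tokens that were neighbours before
  the shift), with per-head relative-position bias, pre-normalization
  blocks, MLP ratio 4, and 2×2 patch merging between stages
  ($C \to 2C \to 4C \to 8C$).

Both branches share the spatial ledger 56/28/14/7 for 224-pixel inputs
(`model_shapes(oct_config(...))` prints it). After each stage a **feature
fusion module** (FFM) joins them:

1. **CRB** — the token grid is reshaped row-major to a map, the CNN map is
   1×1-projected to the transformer stage width, the two are concatenated
   along channels (2× stage width) and refined by a residual 3×3 conv block.
2. **ICAB** — channel attention: per-channel weights
   $w = \sigma(\mathrm{FC}(\mathrm{GAP}(f)))$ rescale every channel.
3. The fused map of the previous stage is 1×1 stride-2 projected and
   **added** (the multi-level chain), the result is split into two channel
   halves, and each half is projected and **added back** to its branch's
   features before the next stage.

The stage-4 fused map feeds the classifier head: global average pooling, a
1024-unit fully connected layer, and softmax over the disease classes.

## Training protocol

Adam with decoupled weight decay 0.05, batch size 128, cosine learning-rate
annealing from $10^{-4}$ to $10^{-6}$ over 100 epochs (desk-scale presets
shrink all three). The loss is the scheduled hybrid

$$L(t) = \begin{cases} L_{focal}, & 0 < t \le n\\ L_{corr}, & n < t \le N \end{cases}, \qquad n = 30,$$

with the focal loss $-\alpha (1-\hat y)^\gamma \log \hat y$ (positives) /
$-(1-\alpha)\hat y^\gamma \log(1-\hat y)$ (negatives) summed over one-hot
coordinates, and the correntropy loss
$1 - \exp(-(y-\hat y)^2/\sigma^2)$ averaged over them. Focal training first
addresses class imbalance; the bounded correntropy branch then finishes
training robustly. Training is considered stabilized at the first epoch
whose relative change in validation loss falls below 0.5 %
(`convergence_epoch()`). Stratified 3-fold cross-validation over the
train+val records (the test split untouched) is available via `kfold_cv()`.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `embed_dim` C | 96 (tiny: 16) | transformer base width; stage widths are C·2^(i−1) |
| `window` M | 7 (tiny: 4) | attention window side, clipped to the grid; shift is ⌊M/2⌋ |
| `cnn_widths` | 256/512/1024/2048 | bottleneck stage output widths (mid = width/4) |
| `alpha`, `gamma` | 0.25, 2 | focal weighting/focusing (canonical values; a per-class α vector is supported) |
| `sigma` | 1 | correntropy kernel width, on the probability scale |
| `switch_epoch` n | 30 | last focal epoch |
| `lr_init`/`lr_min` | 1e-4 / 1e-6 | cosine schedule endpoints |

## Design choices made where the design was open

* **Autodiff substrate.** No deep-learning framework is available to R
  here, and the architecture's value is exactly in its wiring, so the
  package carries a small reverse-mode tape (`R/autodiff.R`) with
  hand-derived backward rules per layer op (im2col convolutions, a fused
  window-attention op, normalizations). All gradients are verified against
  central finite differences in the test suite.
* **Normalization.** The CNN branch normalizes each channel per sample over
  its spatial positions (instance normalization) rather than using running
  batch statistics: inference is then independent of batch composition and
  training is bit-reproducible under any batch assembly. On a degenerate
  1×1 spatial map (the last stage of the 32-pixel micro preset) the
  normalization reduces to its affine transform, since a single position
  carries no distributional information — zeroing it would sever the branch.
* **Zero-fusion degeneracy.** Both halves of the fused map pass through
  learned 1×1 projections before being added back to their branches. With
  every FFM weight zero the module then contributes exactly nothing
  (`k_back ≡ k`, `d_back ≡ d`), a property the tests rely on; with only the
  CNN-side projection the token-side feedback could never be silenced, since
  the CRB's identity skip and the ICAB's σ(0) = 1/2 keep the fused map
  nonzero under zero weights.
* **Multi-level chain direction.** Fused features flow from stage $i-1$
  into stage $i$ (with stride-2 projection). The reverse direction would
  need stage $i{+}1$ outputs while computing stage $i$ and is not realisable
  in one feed-forward pass; `fusion_forward = "none"` disables the chain for
  ablation instead.
* **Stage-4 feedback.** The split-and-add-back of the last FFM has no
  consumer (its fused map goes straight to the classifier), so those two
  projections are omitted rather than carried as dead weights.
* **ICAB "dot product".** Interpreted as per-channel scalar rescaling
  (standard channel attention); a literal inner product would collapse
  spatial structure. The FC is a single layer, not a squeeze–excite
  bottleneck.
* **Correntropy coordinates.** Computed over the full one-hot vector by
  default (`correntropy_on = "true_class"` selects the alternative).
* **Masking constant.** −10⁴, finite for autodiff safety; it underflows to
  exactly zero attention weight in double precision, so masked and
  region-partitioned attention agree to machine precision.
* **Splitting.** 7:2:1 image-wise splits use largest-remainder rounding
  (floor each share, distribute the remainder by fractional part, ties to
  the earlier split), which reproduces the published per-split counts of
  the three public OCT datasets exactly while always summing to the total.
  Patient-grouped splitting is deliberately not the default.

## The synthetic generator

Real OCT datasets cannot ship with the package, so `synthetic_spec()` /
`generate_dataset()` emulate the image-folder layout with layered
"retina band" images: a fixed smooth horizontal band profile (an
anatomy-like scaffold shared by all images) plus one class-specific lesion
motif — bright blob, dark cavity, dome elevation of the bands, or a
vertical band break — at a seeded random position inside the central half,
plus Gaussian pixel noise. Per-image randomness (lesion position, noise) is
drawn from an independent stream derived from the master seed and the
(class, draw) pair, so any single image can be regenerated bit-identically
in isolation. Images are written as lossless PNG so round trips are exact.

The band profile is deliberately identical across images: the lesion motif
is then the only class-correlated structure, which is what makes the
end-to-end checks meaningful — a classifier trained on these images must
read the lesion, and Grad-CAM heatmaps can be scored against the known
lesion position. What the generator does **not** model: speckle statistics
of real OCT, per-patient anatomical variability, the actual appearance of
CNV/DME/drusen pathology, acquisition artefacts. Passing tests therefore
demonstrate that the pipeline's mechanics are correct, not that the
architecture reaches any particular accuracy on clinical data.

## Problem sizes used by the tests and the acceptance script

The suite runs entirely on CPU-sized models: the `micro` preset (32-pixel
images, C = 8) for mechanics and determinism, and the `tiny` preset
(64-pixel images, C = 16, ~2.8 M parameters) for the end-to-end run: 40
training images in batches of 8 for 40 epochs (200 optimisation steps),
which drives training accuracy to 1.0, with the focal→correntropy switch
kept at epoch 30. Grad-CAM localization is evaluated at the stage-2 fused
map (8×8): on 64-pixel inputs it has the same relative resolution as the
stage-4 7×7 map has on 224-pixel inputs, whereas the tiny model's own
stage-4 map is 2×2 and cannot resolve a lesion to within its radius. The
default Grad-CAM layer for full-sized models remains the stage-4 fused map.

A caveat the suite surfaces deliberately: on models this small, trained
this briefly, the *global peak* of a Grad-CAM map is a brittle
localization statistic. Across training seeds the hottest cell often
lands on a corner token rather than the lesion — the behaviour reported
for small vision transformers, where attention concentrates global class
evidence in a few low-information "register" positions — and the
in-box/out-box heat contrast (which the acceptance script also reports)
varies with the seed as well. The localization test is kept at full
strength (peak inside the lesion box in ≥80 % of cases) rather than
weakened, and is expected to fail for many seeds; it documents a genuine
limitation of gradient-based class activation maps on attention models at
desk scale, not a defect of the pipeline (the Grad-CAM computation itself
is verified by a closed-form unit test).

## Known limitations

* Pure-R execution: a 224-pixel forward pass takes seconds; full-protocol
  training (128×100 epochs on tens of thousands of images) is out of reach
  and out of scope — the package's claims are about correctness of the
  method's mechanics, verified by oracles at small scale.
* ImageNet pretraining of the CNN branch is supported only as a
  weight-loading hook (weights must be supplied as a named parameter list);
  no downloader is included.
* The attention implementation favours clarity (per-window loops over BLAS
  matmuls) over fused-kernel speed.
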