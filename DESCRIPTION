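Package: octfusion
Title: Dual-Branch CNN-Transformer Classification of Retinal OCT Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Trains and evaluates a dual-branch image classifier for retinal
    optical coherence tomography (OCT) B-scans. One branch is a residual
    convolutional network capturing local texture; the other is a hierarchical
    shifted-window self-attention (Swin-style) transformer capturing global
    context. A per-stage feature fusion module (channel concatenation with a
    residual block, followed by channel attention) exchanges information
    between the branches, and a multi-level chain forwards fused features
    across stages into a softmax classifier head. Training uses an
    epoch-scheduled hybrid of focal loss and Gaussian-kernel correntropy loss.
    The package includes a reverse-mode automatic differentiation engine in
    base R, a deterministic synthetic OCT-like image generator for end-to-end
    testing, image-folder dataset handling with largest-remainder 7:2:1
    splitting, one-vs-rest evaluation metrics, Grad-CAM heatmaps, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
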