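# Residual CNN branch: a 7x7 stride-2 stem with pooling to the 1/4-resolution
# grid, then four stages of 1x1 -> 3x3 -> 1x1 bottleneck blocks with identity
# or projected skips. Resolution halves stage to stage while channel width
# grows. Normalization is per-channel per-sample (see methods vignette).

cnn_stem_width <- function(cfg) cfg$cnn_widths[1L] %/% 4L

init_cnn_stem <- function(st, cfg) {
  c0 <- cnn_stem_width(cfg)
  init_conv(st, "cnn.stem.conv", 7L, 7L, 3L, c0)
  init_norm(st, "cnn.stem.norm", c0)
}

# ImageTensor (S, S, 3) node -> stage-0 FeatureMap at 1/4 resolution.
fwd_conv_stem <- function(x, cfg, pget) {
  S <- dim(x$val)[1L]
  if (S %% 4L != 0L) stop("input side must be divisible by 4")
  y <- ad_conv2d(x, pget("cnn.stem.conv.W"), pget("cnn.stem.conv.b"),
                 7L, 7L, stride = 2L, pad = 3L)
  y <- ad_channelnorm(y, pget("cnn.stem.norm.g"), pget("cnn.stem.norm.b"))
  y <- ad_relu(y)
  ad_maxpool(y)
}

init_bottleneck <- function(st, prefix, cin, mid, cout, stride) {
  if (mid <= 0L) stop("mid_channels must be positive")
  init_conv(st, paste0(prefix, ".conv1"), 1L, 1L, cin, mid)
  init_norm(st, paste0(prefix, ".n1"), mid)
  init_conv(st, paste0(prefix, ".conv2"), 3L, 3L, mid, mid)
  init_norm(st, paste0(prefix, ".n2"), mid)
  init_conv(st, paste0(prefix, ".conv3"), 1L, 1L, mid, cout)
  init_norm(st, paste0(prefix, ".n3"), cout)
  if (cin != cout || stride != 1L) {
    init_conv(st, paste0(prefix, ".proj"), 1L, 1L, cin, cout)
    init_norm(st, paste0(prefix, ".np"), cout)
  }
}

# Bottleneck residual block: activation(F(x) + P(x)) with F the
# 1x1 -> 3x3(stride) -> 1x1 path and P identity or a stride-matched 1x1
# projection when shapes change.
fwd_bottleneck <- function(x, prefix, stride, params, pget) {
  y <- ad_conv2d(x, pget(paste0(prefix, ".conv1.W")), pget(paste0(prefix, ".conv1.b")), 1L, 1L)
  y <- ad_relu(ad_channelnorm(y, pget(paste0(prefix, ".n1.g")), pget(paste0(prefix, ".n1.b"))))
  y <- ad_conv2d(y, pget(paste0(prefix, ".conv2.W")), pget(paste0(prefix, ".conv2.b")),
                 3L, 3L, stride = stride, pad = 1L)
  y <- ad_relu(ad_channelnorm(y, pget(paste0(prefix, ".n2.g")), pget(paste0(prefix, ".n2.b"))))
  y <- ad_conv2d(y, pget(paste0(prefix, ".conv3.W")), pget(paste0(prefix, ".conv3.b")), 1L, 1L)
  y <- ad_channelnorm(y, pget(paste0(prefix, ".n3.g")), pget(paste0(prefix, ".n3.b")))
  skip <- if (!is.null(params[[paste0(prefix, ".proj.W")]])) {
    p <- ad_conv1x1(x, pget(paste0(prefix, ".proj.W")), pget(paste0(prefix, ".proj.b")),
                    stride = stride)
    ad_channelnorm(p, pget(paste0(prefix, ".np.g")), pget(paste0(prefix, ".np.b")))
  } else {
    x
  }
  ad_relu(ad_add(y, skip))
}

cnn_stage_blocks <- function(cfg, stage) {
  rep_len(cfg$cnn_blocks_per_stage, 4L)[stage]
}

init_cnn_stage <- function(st, stage, cfg) {
  cin <- if (stage == 1L) cnn_stem_width(cfg) else cfg$cnn_widths[stage - 1L]
  cout <- cfg$cnn_widths[stage]
  mid <- cout %/% 4L
  for (b in seq_len(cnn_stage_blocks(cfg, stage))) {
    stride <- if (b == 1L && stage > 1L) 2L else 1L
    init_bottleneck(st, sprintf("cnn.s%d.b%d", stage, b),
                    if (b == 1L) cin else cout, mid, cout, stride)
    cin <- cout
  }
}

# One CNN stage: the first block downsamples (stride 2) for stages 2-4.
fwd_cnn_stage <- function(x, stage, cfg, params, pget) {
  if (!stage %in% 1:4) stop("stage must be in 1..4")
  for (b in seq_len(cnn_stage_blocks(cfg, stage))) {
    stride <- if (b == 1L && stage > 1L) 2L else 1L
    x <- fwd_bottleneck(x, sprintf("cnn.s%d.b%d", stage, b), stride, params, pget)
  }
  x
}
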