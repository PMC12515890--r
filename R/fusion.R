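# Feature fusion module (FFM) and full-model assembly. Per stage, the CRB
# concatenates the (projected) CNN map with the reshaped token grid along
# channels and refines it with a residual conv block; the ICAB re-weights
# channels via global-average-pooled sigmoid attention. The fused map is split
# back into two halves that are added to each branch's features, and is also
# forwarded (1x1 stride-2 projection) into the next stage's fusion output.

#' Reshape a token matrix into a spatial feature map
#'
#' Tokens are stored row-major over the grid: token 1 maps to grid position
#' (1, 1), token 2 to (1, 2), and so on. The inverse is [map_to_tokens()];
#' the round trip is exact.
#'
#' @param tokens an `(h*w) x c` matrix.
#' @param h,w grid dimensions with `h * w == nrow(tokens)`.
#' @return An `h x w x c` array.
#' @export
tokens_to_map <- function(tokens, h, w) {
  if (nrow(tokens) != h * w) stop("token count does not match h * w")
  idx <- t2m_index(h, w, ncol(tokens))
  out <- tokens[idx]
  dim(out) <- c(h, w, ncol(tokens))
  out
}

#' Flatten a spatial feature map into a token matrix
#'
#' @param map an `h x w x c` array.
#' @return An `(h*w) x c` matrix in row-major grid order.
#' @seealso [tokens_to_map()]
#' @export
map_to_tokens <- function(map) {
  d <- dim(map)
  idx <- m2t_index(d[1L], d[2L], d[3L])
  out <- map[idx]
  dim(out) <- c(d[1L] * d[2L], d[3L])
  out
}

.t2m_cache <- new.env(parent = emptyenv())

t2m_index <- function(h, w, c) {
  key <- paste("t", h, w, c, sep = "_")
  idx <- .t2m_cache[[key]]
  if (!is.null(idx)) return(idx)
  i <- rep(seq_len(h), times = w)
  j <- rep(seq_len(w), each = h)
  t <- (i - 1L) * w + j
  idx <- as.vector(outer(t, (seq_len(c) - 1L) * (h * w), "+"))
  .t2m_cache[[key]] <- idx
  idx
}

m2t_index <- function(h, w, c) {
  key <- paste("m", h, w, c, sep = "_")
  idx <- .t2m_cache[[key]]
  if (!is.null(idx)) return(idx)
  t <- seq_len(h * w)
  i <- (t - 1L) %/% w + 1L
  j <- (t - 1L) %% w + 1L
  sp <- i + (j - 1L) * h
  idx <- as.vector(outer(sp, (seq_len(c) - 1L) * (h * w), "+"))
  .t2m_cache[[key]] <- idx
  idx
}

ad_tokens_to_map <- function(k, h, w) {
  c <- ncol(k$val)
  ad_reindex(k, t2m_index(h, w, c), c(h, w, c))
}

ad_map_to_tokens <- function(m) {
  d <- dim(m$val)
  ad_reindex(m, m2t_index(d[1L], d[2L], d[3L]), c(d[1L] * d[2L], d[3L]))
}

# Channel concatenation of two (h, w, c) maps.
ad_cat_channels <- function(a, b) {
  da <- dim(a$val); db <- dim(b$val)
  am <- ad_reshape(a, c(da[1L] * da[2L], da[3L]))
  bm <- ad_reshape(b, c(db[1L] * db[2L], db[3L]))
  ad_reshape(ad_cbind(am, bm), c(da[1L], da[2L], da[3L] + db[3L]))
}

ad_channel_slice <- function(x, cidx) {
  d <- dim(x$val)
  xm <- ad_reshape(x, c(d[1L] * d[2L], d[3L]))
  ad_reshape(ad_cols(xm, cidx), c(d[1L], d[2L], length(cidx)))
}

## ---- FFM components --------------------------------------------------------

init_ffm <- function(st, stage, cfg) {
  s <- swin_widths(cfg)[stage]
  wid <- cfg$cnn_widths[stage]
  pre <- sprintf("ffm.s%d", stage)
  init_conv(st, paste0(pre, ".dproj"), 1L, 1L, wid, s)
  init_conv(st, paste0(pre, ".crb.conv1"), 3L, 3L, 2L * s, 2L * s)
  init_norm(st, paste0(pre, ".crb.n1"), 2L * s)
  init_conv(st, paste0(pre, ".crb.conv2"), 3L, 3L, 2L * s, 2L * s)
  init_norm(st, paste0(pre, ".crb.n2"), 2L * s)
  init_linear(st, paste0(pre, ".icab.fc"), 2L * s, 2L * s)
  if (stage < 4L) {
    # stage-4 branch feedback has no consumer (the fused map goes straight
    # to the classifier), so its projections are not created
    init_conv(st, paste0(pre, ".kback"), 1L, 1L, s, s)
    init_conv(st, paste0(pre, ".dback"), 1L, 1L, s, wid)
  }
  if (stage > 1L && cfg$fusion_forward == "down") {
    sprev <- swin_widths(cfg)[stage - 1L]
    init_conv(st, paste0(pre, ".prev"), 1L, 1L, 2L * sprev, 2L * s)
  }
}

# Concatenation-and-residual block: channel concat then a residual
# 3x3/norm/activation x2 refinement at constant width.
fwd_crb <- function(k_map, d_map, pre, pget) {
  x <- ad_cat_channels(k_map, d_map)
  y <- ad_conv2d(x, pget(paste0(pre, ".crb.conv1.W")),
                 pget(paste0(pre, ".crb.conv1.b")), 3L, 3L, pad = 1L)
  y <- ad_relu(ad_channelnorm(y, pget(paste0(pre, ".crb.n1.g")),
                              pget(paste0(pre, ".crb.n1.b"))))
  y <- ad_conv2d(y, pget(paste0(pre, ".crb.conv2.W")),
                 pget(paste0(pre, ".crb.conv2.b")), 3L, 3L, pad = 1L)
  y <- ad_channelnorm(y, pget(paste0(pre, ".crb.n2.g")),
                      pget(paste0(pre, ".crb.n2.b")))
  ad_relu(ad_add(x, y))
}

# Improved channel attention block: sigmoid(FC(GAP(f))) scales each channel.
fwd_icab <- function(f, pre, pget) {
  g <- ad_gap(f)
  wts <- ad_sigmoid(ad_addrows(ad_matmul(g, pget(paste0(pre, ".icab.fc.W"))),
                               pget(paste0(pre, ".icab.fc.b"))))
  ad_scale_channels(f, wts)
}

# One fusion step at `stage`: returns the fed-back branch features and the
# fused map (with the multi-level contribution from `prev_fused` added in).
fwd_ffm_step <- function(k, d, prev_fused, stage, cfg, pget,
                         feedback = TRUE) {
  s <- swin_widths(cfg)[stage]
  g <- stage_grids(cfg)[stage]
  pre <- sprintf("ffm.s%d", stage)
  d_proj <- ad_conv1x1(d, pget(paste0(pre, ".dproj.W")), pget(paste0(pre, ".dproj.b")))
  k_map <- ad_tokens_to_map(k, g, g)
  f <- fwd_crb(k_map, d_proj, pre, pget)
  f <- fwd_icab(f, pre, pget)
  if (!is.null(prev_fused)) {
    down <- ad_conv1x1(prev_fused, pget(paste0(pre, ".prev.W")),
                       pget(paste0(pre, ".prev.b")), stride = 2L)
    f <- ad_add(f, down)
  }
  if (!feedback) return(list(k_back = k, d_back = d, fused = f))
  k_half <- ad_channel_slice(f, 1:s)
  d_half <- ad_channel_slice(f, s + (1:s))
  # both feedback halves pass through learned 1x1 projections so that a
  # zero-weight FFM contributes exactly nothing to either branch
  k_half <- ad_conv1x1(k_half, pget(paste0(pre, ".kback.W")),
                       pget(paste0(pre, ".kback.b")))
  k_back <- ad_add(k, ad_map_to_tokens(k_half))
  d_back <- ad_add(d, ad_conv1x1(d_half, pget(paste0(pre, ".dback.W")),
                                 pget(paste0(pre, ".dback.b"))))
  list(k_back = k_back, d_back = d_back, fused = f)
}

init_classifier <- function(st, cfg) {
  cin <- 2L * swin_widths(cfg)[4L]
  init_linear(st, "head.fc1", cin, cfg$classifier_hidden)
  init_linear(st, "head.fc2", cfg$classifier_hidden, cfg$num_classes)
}

# Stage-4 fused map -> class probabilities (GAP, 1024-unit FC, softmax head).
fwd_classifier <- function(f4, cfg, pget) {
  if (cfg$num_classes < 2L) stop("classifier needs at least 2 classes")
  g <- ad_gap(f4)
  h <- ad_relu(ad_addrows(ad_matmul(g, pget("head.fc1.W")), pget("head.fc1.b")))
  logits <- ad_addrows(ad_matmul(h, pget("head.fc2.W")), pget("head.fc2.b"))
  list(logits = logits, prob = ad_softmax(logits))
}

## ---- model build and forward -----------------------------------------------

#' Build a dual-branch OCT classifier with freshly initialised weights
#'
#' @param cfg an [oct_config()].
#' @param seed integer seed controlling weight initialisation.
#' @return An object of class `oct_model`: a list with `cfg` and the named
#'   parameter list `params`.
#' @examples
#' m <- oct_model(oct_config(2, preset = "micro"), seed = 1)
#' format(n_params(m), big.mark = ",")
#' @export
oct_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "oct_config"))
  st <- new_params()
  with_seed(as.integer(seed), {
    init_patch_embed(st, cfg)
    widths <- swin_widths(cfg)
    grids <- stage_grids(cfg)
    for (i in 1:4) {
      if (i > 1L) init_patch_merge(st, sprintf("swin.m%d", i), widths[i - 1L])
      M <- stage_window(grids[i], cfg$window)$M
      for (b in seq_len(cfg$depths[i])) {
        init_swin_block(st, sprintf("swin.s%d.b%d", i, b), widths[i], M,
                        cfg$heads[i])
      }
    }
    init_cnn_stem(st, cfg)
    for (i in 1:4) init_cnn_stage(st, i, cfg)
    for (i in 1:4) init_ffm(st, i, cfg)
    init_classifier(st, cfg)
  })
  structure(list(cfg = cfg, params = st$p), class = "oct_model")
}

#' Number of trainable parameters
#' @param model an `oct_model` or `oct_fit`.
#' @export
n_params <- function(model) {
  p <- if (inherits(model, "oct_fit")) model$model$params else model$params
  sum(vapply(p, length, 0))
}

#' @export
print.oct_model <- function(x, ...) {
  cat(sprintf("oct_model: %s parameters\n", format(n_params(x), big.mark = ",")))
  print(x$cfg)
  invisible(x)
}

#' Forward pass of the dual-branch network
#'
#' Runs both branches stage by stage, applying the feature fusion module after
#' each stage and feeding the fused halves back into the branches, then
#' classifies from the stage-4 fused map.
#'
#' @param model an [oct_model()] (or an `oct_fit`, whose trained weights are
#'   used).
#' @param x a preprocessed image tensor (`S x S x 3` array, see
#'   [preprocess()]).
#' @param record keep the autodiff tape and intermediate nodes (needed for
#'   gradients and Grad-CAM).
#' @return A list with `prob` (length-K probability vector), `logits`, and
#'   `state`: per-stage fused maps plus branch features (arrays; tape nodes
#'   when `record = TRUE` under `state$nodes`).
#' @export
oct_forward <- function(model, x, record = FALSE) {
  if (inherits(model, "oct_fit")) model <- model$model
  cfg <- model$cfg
  d <- dim(x)
  if (is.null(d) || length(d) != 3L || d[1L] != cfg$image_size ||
      d[2L] != cfg$image_size || d[3L] != 3L) {
    stop("input must be a ", cfg$image_size, "x", cfg$image_size, "x3 tensor")
  }
  ad_reset(record = record)
  pget <- par_getter(model$params)
  xn <- ad_leaf(x)
  grids <- stage_grids(cfg)
  k <- fwd_patch_partition(xn, cfg, pget)
  dmap <- fwd_conv_stem(xn, cfg, pget)
  fused_prev <- NULL
  nodes <- list(input = xn)
  for (i in 1:4) {
    if (i > 1L) k <- fwd_patch_merging(k, grids[i - 1L], grids[i - 1L],
                                       sprintf("swin.m%d", i), pget)
    k <- fwd_swin_stage(k, grids[i], grids[i], i, cfg, pget)
    dmap <- fwd_cnn_stage(dmap, i, cfg, model$params, pget)
    chain <- if (cfg$fusion_forward == "down") fused_prev else NULL
    step <- fwd_ffm_step(k, dmap, chain, i, cfg, pget, feedback = i < 4L)
    nodes[[sprintf("swin%d", i)]] <- k
    nodes[[sprintf("cnn%d", i)]] <- dmap
    nodes[[sprintf("fused%d", i)]] <- step$fused
    k <- step$k_back
    dmap <- step$d_back
    fused_prev <- step$fused
  }
  head <- fwd_classifier(fused_prev, cfg, pget)
  nodes$logits <- head$logits
  nodes$prob <- head$prob
  list(
    prob = as.vector(head$prob$val),
    logits = as.vector(head$logits$val),
    state = list(
      fused = lapply(1:4, function(i) nodes[[sprintf("fused%d", i)]]$val),
      nodes = if (record) nodes else NULL
    )
  )
}

#' Load external weights into a model
#'
#' Replaces named parameter arrays (e.g. a pretrained CNN backbone) after
#' checking that every supplied name exists and matches the stored
#' dimensions. Weights not mentioned keep their current values.
#'
#' @param model an [oct_model()] or [oct_fit()].
#' @param weights named list of arrays, a subset of `coef(model)`.
#' @return The model with the weights replaced.
#' @export
set_weights <- function(model, weights) {
  target <- if (inherits(model, "oct_fit")) model$model$params else model$params
  unknown <- setdiff(names(weights), names(target))
  if (length(unknown)) {
    stop("unknown parameter name(s): ", paste(utils::head(unknown, 3), collapse = ", "))
  }
  for (nm in names(weights)) {
    if (!identical(dim1(weights[[nm]]), dim1(target[[nm]]))) {
      stop("dimension mismatch for ", nm)
    }
    target[[nm]] <- weights[[nm]]
  }
  if (inherits(model, "oct_fit")) model$model$params <- target
  else model$params <- target
  model
}
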