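# Shifted-window self-attention branch: patch embedding, window / shifted
# window multi-head attention with cyclic-shift masking and relative position
# bias, MLP blocks in pre-normalization layout, and patch merging between
# stages. Token matrices are (h*w) x c with tokens in row-major grid order
# (token 1 at grid (1,1), token 2 at (1,2), ...).

.win_cache <- new.env(parent = emptyenv())

# Window geometry for an h x w grid, window M, cyclic shift s:
# roll permutation, per-window token indices, relative-position index table.
win_geom <- function(h, w, M, s) {
  key <- paste(h, w, M, s, sep = "_")
  g <- .win_cache[[key]]
  if (!is.null(g)) return(g)
  stopifnot(h %% M == 0L, w %% M == 0L, s >= 0L, s < M)
  hw <- h * w
  t0 <- 0:(hw - 1L)
  i <- t0 %/% w
  j <- t0 %% w
  # rolled token r takes original token at (i+s, j+s) mod grid
  perm <- ((i + s) %% h) * w + ((j + s) %% w) + 1L
  iperm <- integer(hw)
  iperm[perm] <- seq_len(hw)
  nw <- (h %/% M) * (w %/% M)
  widx <- vector("list", nw)
  k <- 0L
  for (a in 0:(h %/% M - 1L)) for (b in 0:(w %/% M - 1L)) {
    k <- k + 1L
    di <- rep(0:(M - 1L), each = M)
    dj <- rep(0:(M - 1L), times = M)
    widx[[k]] <- (a * M + di) * w + (b * M + dj) + 1L
  }
  di <- rep(0:(M - 1L), each = M)
  dj <- rep(0:(M - 1L), times = M)
  ridx <- outer(di, di, "-") + (M - 1L)
  ridx <- ridx * (2L * M - 1L) + outer(dj, dj, "-") + (M - 1L) + 1L
  g <- list(perm = perm, iperm = iperm, widx = widx, ridx = ridx, nw = nw)
  .win_cache[[key]] <- g
  g
}

#' Additive attention masks for shifted-window self-attention
#'
#' Builds the per-window additive bias matrices that restrict attention, after
#' a cyclic shift by `shift`, to token pairs that were spatial neighbours
#' before the shift. Grid cells are labelled by their pre-shift region (the
#' 3 x 3 decomposition with cuts at `h - window`, `h - shift` and likewise for
#' columns, evaluated in rolled coordinates); within a window, entry (i, j) is
#' 0 when the labels match and `-1e4` otherwise. With `shift = 0` every entry
#' is 0.
#'
#' @param h,w token grid dimensions, each divisible by `window`.
#' @param window window side length M.
#' @param shift cyclic shift s, `0 <= s < window`.
#' @return A list with one `(window^2) x (window^2)` matrix per window, in
#'   row-major window order.
#' @examples
#' m <- build_shift_mask(8, 8, 4, 2)
#' length(m)            # 4 windows
#' all(m[[1]] == 0)     # the non-wrapping window is unmasked
#' @export
build_shift_mask <- function(h, w, window, shift) {
  h <- as.integer(h); w <- as.integer(w)
  M <- as.integer(window); s <- as.integer(shift)
  if (s >= M || s < 0L) stop("shift must satisfy 0 <= shift < window")
  if (h %% M != 0L || w %% M != 0L) {
    stop("grid dimensions must be divisible by the window size")
  }
  geo <- win_geom(h, w, M, s)
  if (s == 0L) {
    z <- matrix(0, M * M, M * M)
    return(rep(list(z), geo$nw))
  }
  region <- function(i, n) ifelse(i < n - M, 0L, ifelse(i < n - s, 1L, 2L))
  t0 <- 0:(h * w - 1L)
  lab <- region(t0 %/% w, h) * 3L + region(t0 %% w, w)
  lapply(geo$widx, function(ti) {
    l <- lab[ti]
    m <- outer(l, l, "!=") * (-1e4)
    m
  })
}

# Fused window multi-head self-attention tape op. `x` holds (h*w) x c tokens;
# returns the projected attention output (no residual). Weight arguments are
# tape nodes: Wqkv (c x 3c), bqkv (3c), Wo (c x c), bo (c), rtab
# ((2M-1)^2 x heads) relative-position bias table.
ad_window_msa <- function(x, h, w, M, s, heads, Wqkv, bqkv, Wo, bo, rtab) {
  geo <- win_geom(h, w, M, s)
  cdim <- ncol(x$val)
  stopifnot(cdim %% heads == 0L)
  dh <- cdim %/% heads
  scale <- 1 / sqrt(dh)
  masks <- if (s > 0L) build_shift_mask(h, w, M, s) else NULL
  Xs <- x$val[geo$perm, , drop = FALSE]
  QKV <- sweep(Xs %*% Wqkv$val, 2L, bqkv$val, "+")
  Q <- QKV[, 1:cdim, drop = FALSE]
  K <- QKV[, cdim + (1:cdim), drop = FALSE]
  V <- QKV[, 2L * cdim + (1:cdim), drop = FALSE]
  rtv <- rtab$val
  Bh <- lapply(seq_len(heads), function(hd) {
    matrix(rtv[geo$ridx, hd], M * M, M * M)
  })
  Plist <- vector("list", geo$nw * heads)
  Oall <- matrix(0, nrow(Xs), cdim)
  for (wi in seq_len(geo$nw)) {
    ti <- geo$widx[[wi]]
    for (hd in seq_len(heads)) {
      hc <- (hd - 1L) * dh + (1:dh)
      q <- Q[ti, hc, drop = FALSE]
      k <- K[ti, hc, drop = FALSE]
      v <- V[ti, hc, drop = FALSE]
      S <- tcrossprod(q, k) * scale + Bh[[hd]]
      if (!is.null(masks)) S <- S + masks[[wi]]
      S <- S - apply(S, 1L, max)
      E <- exp(S)
      P <- E / rowSums(E)
      Plist[[(wi - 1L) * heads + hd]] <- P
      Oall[ti, hc] <- P %*% v
    }
  }
  Yr <- sweep(Oall %*% Wo$val, 2L, bo$val, "+")
  val <- Yr[geo$iperm, , drop = FALSE]
  Wqkv_v <- Wqkv$val; Wo_v <- Wo$val
  ad_node(val, c(x$id, Wqkv$id, bqkv$id, Wo$id, bo$id, rtab$id), function(g) {
    dYr <- g[geo$perm, , drop = FALSE]
    dOall <- tcrossprod(dYr, Wo_v)
    dWo <- crossprod(Oall, dYr)
    dbo <- colSums(dYr)
    dQ <- matrix(0, nrow(Xs), cdim)
    dK <- matrix(0, nrow(Xs), cdim)
    dV <- matrix(0, nrow(Xs), cdim)
    dtab <- matrix(0, nrow(rtv), heads)
    rvec <- as.vector(geo$ridx)
    for (hd in seq_len(heads)) {
      hc <- (hd - 1L) * dh + (1:dh)
      dSsum <- 0
      for (wi in seq_len(geo$nw)) {
        ti <- geo$widx[[wi]]
        P <- Plist[[(wi - 1L) * heads + hd]]
        q <- Q[ti, hc, drop = FALSE]
        k <- K[ti, hc, drop = FALSE]
        v <- V[ti, hc, drop = FALSE]
        dO <- dOall[ti, hc, drop = FALSE]
        dVw <- crossprod(P, dO)
        dP <- tcrossprod(dO, v)
        dS <- P * (dP - rowSums(dP * P))
        dSsum <- dSsum + dS
        dQ[ti, hc] <- dS %*% k * scale
        dK[ti, hc] <- crossprod(dS, q) * scale
        dV[ti, hc] <- dVw
      }
      rs <- rowsum(as.vector(dSsum), group = rvec)
      dtab[as.integer(rownames(rs)), hd] <- rs[, 1L]
    }
    dQKV <- cbind(dQ, dK, dV)
    dXs <- tcrossprod(dQKV, Wqkv_v)
    dWqkv <- crossprod(Xs, dQKV)
    dbqkv <- colSums(dQKV)
    dx <- dXs[geo$iperm, , drop = FALSE]
    list(dx, dWqkv, dbqkv, dWo, dbo, dtab)
  })
}

## ---- parameter initialisation helpers --------------------------------------

new_params <- function() {
  e <- new.env(parent = emptyenv())
  e$p <- list()
  e
}

add_par <- function(st, name, val) {
  st$p[[name]] <- val
  invisible(NULL)
}

init_linear <- function(st, prefix, fin, fout, bias = TRUE, sd = 0.02) {
  add_par(st, paste0(prefix, ".W"), matrix(stats::rnorm(fin * fout, 0, sd), fin, fout))
  if (bias) add_par(st, paste0(prefix, ".b"), numeric(fout))
}

init_norm <- function(st, prefix, n) {
  add_par(st, paste0(prefix, ".g"), rep(1, n))
  add_par(st, paste0(prefix, ".b"), numeric(n))
}

# Kaiming-style init for a conv weight matrix ((kh*kw*cin) x cout).
init_conv <- function(st, prefix, kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  sd <- sqrt(2 / fan_in)
  add_par(st, paste0(prefix, ".W"),
          matrix(stats::rnorm(fan_in * cout, 0, sd), fan_in, cout))
  add_par(st, paste0(prefix, ".b"), numeric(cout))
}

# Parameter fetch bound to a parameter list for one forward pass.
par_getter <- function(params) {
  function(name) {
    v <- params[[name]]
    if (is.null(v)) stop("missing parameter: ", name)
    ad_param(name, v)
  }
}

## ---- patch embedding and merging -------------------------------------------

.patch_cache <- new.env(parent = emptyenv())

patch_index <- function(S, p) {
  key <- paste(S, p, sep = "_")
  idx <- .patch_cache[[key]]
  if (!is.null(idx)) return(idx)
  gh <- S %/% p
  ntok <- gh * gh
  q <- p * p * 3L
  idx <- matrix(0L, ntok, q)
  t <- 0L
  for (gr in 0:(gh - 1L)) for (gc in 0:(gh - 1L)) {
    t <- t + 1L
    col <- 0L
    for (ch in 0:2) for (pj in 0:(p - 1L)) for (pi in 0:(p - 1L)) {
      col <- col + 1L
      idx[t, col] <- (gr * p + pi + 1L) + (gc * p + pj) * S + ch * S * S
    }
  }
  .patch_cache[[key]] <- idx
  idx
}

init_patch_embed <- function(st, cfg) {
  p <- cfg$patch_size
  init_linear(st, "swin.embed", 3L * p * p, cfg$embed_dim)
  init_norm(st, "swin.embed.ln", cfg$embed_dim)
}

# Image (S, S, 3) node -> TokenGrid node ((S/p)^2 x C), with embedding LN.
fwd_patch_partition <- function(x, cfg, pget) {
  S <- dim(x$val)[1L]
  p <- cfg$patch_size
  if (S %% p != 0L) stop("image side must be divisible by the patch size")
  idx <- patch_index(S, p)
  raw <- ad_reindex(x, as.vector(idx), c(nrow(idx), ncol(idx)))
  emb <- ad_addrows(ad_matmul(raw, pget("swin.embed.W")), pget("swin.embed.b"))
  ad_layernorm(emb, pget("swin.embed.ln.g"), pget("swin.embed.ln.b"))
}

.merge_cache <- new.env(parent = emptyenv())

merge_index <- function(h, w) {
  key <- paste(h, w, sep = "_")
  g <- .merge_cache[[key]]
  if (!is.null(g)) return(g)
  h2 <- h %/% 2L; w2 <- w %/% 2L
  t0 <- 0:(h2 * w2 - 1L)
  i2 <- t0 %/% w2; j2 <- t0 %% w2
  tok <- function(i, j) i * w + j + 1L
  g <- list(
    g0 = tok(2L * i2, 2L * j2),
    g1 = tok(2L * i2 + 1L, 2L * j2),
    g2 = tok(2L * i2, 2L * j2 + 1L),
    g3 = tok(2L * i2 + 1L, 2L * j2 + 1L)
  )
  .merge_cache[[key]] <- g
  g
}

init_patch_merge <- function(st, prefix, cdim) {
  init_norm(st, paste0(prefix, ".ln"), 4L * cdim)
  init_linear(st, paste0(prefix, ".red"), 4L * cdim, 2L * cdim, bias = FALSE)
}

# TokenGrid (h*w) x c -> ((h/2)*(w/2)) x 2c via 2x2 neighbourhood concat,
# normalization and linear reduction.
fwd_patch_merging <- function(x, h, w, prefix, pget) {
  if (h %% 2L != 0L || w %% 2L != 0L) stop("patch merging needs even grid dims")
  gi <- merge_index(h, w)
  cat4 <- ad_cbind(ad_rows(x, gi$g0), ad_rows(x, gi$g1),
                   ad_rows(x, gi$g2), ad_rows(x, gi$g3))
  ln <- ad_layernorm(cat4, pget(paste0(prefix, ".ln.g")), pget(paste0(prefix, ".ln.b")))
  ad_matmul(ln, pget(paste0(prefix, ".red.W")))
}

## ---- transformer blocks ----------------------------------------------------

init_swin_block <- function(st, prefix, cdim, M, heads) {
  init_norm(st, paste0(prefix, ".ln1"), cdim)
  init_linear(st, paste0(prefix, ".qkv"), cdim, 3L * cdim)
  init_linear(st, paste0(prefix, ".proj"), cdim, cdim)
  add_par(st, paste0(prefix, ".rtab"), matrix(0, (2L * M - 1L)^2, heads))
  init_norm(st, paste0(prefix, ".ln2"), cdim)
  init_linear(st, paste0(prefix, ".fc1"), cdim, 4L * cdim)
  init_linear(st, paste0(prefix, ".fc2"), 4L * cdim, cdim)
}

# One pre-norm transformer block: x + WMSA(LN(x)), then x + MLP(LN(x)).
fwd_swin_block <- function(x, h, w, M, s, heads, prefix, pget) {
  ln1 <- ad_layernorm(x, pget(paste0(prefix, ".ln1.g")), pget(paste0(prefix, ".ln1.b")))
  att <- ad_window_msa(ln1, h, w, M, s, heads,
                       pget(paste0(prefix, ".qkv.W")), pget(paste0(prefix, ".qkv.b")),
                       pget(paste0(prefix, ".proj.W")), pget(paste0(prefix, ".proj.b")),
                       pget(paste0(prefix, ".rtab")))
  x1 <- ad_add(x, att)
  ln2 <- ad_layernorm(x1, pget(paste0(prefix, ".ln2.g")), pget(paste0(prefix, ".ln2.b")))
  hdn <- ad_gelu(ad_addrows(ad_matmul(ln2, pget(paste0(prefix, ".fc1.W"))),
                            pget(paste0(prefix, ".fc1.b"))))
  mlp <- ad_addrows(ad_matmul(hdn, pget(paste0(prefix, ".fc2.W"))),
                    pget(paste0(prefix, ".fc2.b")))
  ad_add(x1, mlp)
}

# Effective window and shift for a grid: the window is clipped to the grid
# side and shifting is disabled when a single window covers the grid.
stage_window <- function(h, M) {
  h <- as.integer(h)
  Me <- min(as.integer(M), h)
  if (h %% Me != 0L) stop("grid side ", h, " not divisible by window ", Me)
  list(M = Me, shift = if (Me < h) Me %/% 2L else 0L)
}

# `depth` alternating W-MSA / SW-MSA blocks at constant grid dims.
fwd_swin_stage <- function(x, h, w, stage, cfg, pget) {
  depth <- cfg$depths[stage]
  if (depth %% 2L != 0L) stop("stage depth must be even (W-MSA/SW-MSA pairs)")
  sw <- stage_window(h, cfg$window)
  for (b in seq_len(depth)) {
    s <- if (b %% 2L == 0L) sw$shift else 0L
    x <- fwd_swin_block(x, h, w, sw$M, s, cfg$heads[stage],
                        sprintf("swin.s%d.b%d", stage, b), pget)
  }
  x
}

#' Window / shifted-window multi-head self-attention on a token grid
#'
#' Functional form of the attention sub-layer: cyclically rolls the grid by
#' the shift, partitions it into non-overlapping windows, applies per-window
#' multi-head scaled-dot-product attention with relative-position bias (and
#' the cyclic-shift mask when `shift > 0`), rolls back and applies the output
#' projection. Returns the attention output (no residual added).
#'
#' @param tokens `(h*w) x c` token matrix in row-major grid order.
#' @param h,w grid dimensions, divisible by `window`.
#' @param window window side M.
#' @param shift cyclic shift s (`0 <= s < window`).
#' @param heads number of attention heads (must divide c).
#' @param weights list with `Wqkv` (`c x 3c`), `bqkv` (`3c`), `Wo` (`c x c`),
#'   `bo` (`c`) and `rtab` (`(2M-1)^2 x heads` relative-position bias table).
#' @return `(h*w) x c` matrix.
#' @export
window_msa <- function(tokens, h, w, window, shift, heads, weights) {
  if (ncol(tokens) %% heads != 0L) stop("heads must divide the token width")
  ad_reset(record = FALSE)
  out <- ad_window_msa(ad_const(tokens), as.integer(h), as.integer(w),
                       as.integer(window), as.integer(shift),
                       as.integer(heads),
                       ad_const(weights$Wqkv), ad_const(weights$bqkv),
                       ad_const(weights$Wo), ad_const(weights$bo),
                       ad_const(weights$rtab))
  out$val
}
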