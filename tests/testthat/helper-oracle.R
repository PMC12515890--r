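# Independent brute-force oracles, written with plain loops and no reuse of
# the package's geometry code.

# Region label of a 0-based grid coordinate under the cyclic-shift
# decomposition (cuts at n - M and n - s).
oracle_region <- function(i, n, M, s) {
  if (i < n - M) 0L else if (i < n - s) 1L else 2L
}

# Full window/shifted-window attention computed region-by-region: roll the
# grid, and within every window run unmasked softmax attention independently
# on each group of tokens sharing a pre-shift region label (with the same
# relative-position bias entries). Equivalent to the masked computation.
oracle_window_attention <- function(x, h, w, M, s, heads, wts) {
  cdim <- ncol(x)
  dh <- cdim %/% heads
  hw <- h * w
  rolled <- matrix(0, hw, cdim)
  for (t in 1:hw) {
    i <- (t - 1) %/% w; j <- (t - 1) %% w
    rolled[t, ] <- x[((i + s) %% h) * w + ((j + s) %% w) + 1, ]
  }
  qkv <- rolled %*% wts$Wqkv + matrix(wts$bqkv, hw, 3 * cdim, byrow = TRUE)
  O <- matrix(0, hw, cdim)
  for (a in 0:(h / M - 1)) for (b in 0:(w / M - 1)) {
    toks <- integer(0); di <- integer(0); dj <- integer(0); lab <- integer(0)
    for (u in 0:(M - 1)) for (v in 0:(M - 1)) {
      i <- a * M + u; j <- b * M + v
      toks <- c(toks, i * w + j + 1)
      di <- c(di, u); dj <- c(dj, v)
      lab <- c(lab, oracle_region(i, h, M, s) * 3L + oracle_region(j, w, M, s))
    }
    for (l in unique(lab)) {
      sel <- which(lab == l)
      for (hd in 1:heads) {
        cols <- (hd - 1) * dh + (1:dh)
        q <- qkv[toks[sel], cols, drop = FALSE]
        k <- qkv[toks[sel], cdim + cols, drop = FALSE]
        v <- qkv[toks[sel], 2 * cdim + cols, drop = FALSE]
        B <- matrix(0, length(sel), length(sel))
        for (uu in seq_along(sel)) for (vv in seq_along(sel)) {
          r <- (di[sel[uu]] - di[sel[vv]] + M - 1) * (2 * M - 1) +
            (dj[sel[uu]] - dj[sel[vv]] + M - 1) + 1
          B[uu, vv] <- wts$rtab[r, hd]
        }
        S <- q %*% t(k) / sqrt(dh) + B
        P <- exp(S - apply(S, 1, max))
        P <- P / rowSums(P)
        O[toks[sel], cols] <- P %*% v
      }
    }
  }
  Y <- O %*% wts$Wo + matrix(wts$bo, hw, cdim, byrow = TRUE)
  out <- matrix(0, hw, cdim)
  for (t in 1:hw) {
    i <- (t - 1) %/% w; j <- (t - 1) %% w
    out[((i + s) %% h) * w + ((j + s) %% w) + 1, ] <- Y[t, ]
  }
  out
}

# Brute-force count of masked (-LARGE) entries over all windows.
oracle_mask_count <- function(h, w, M, s) {
  cnt <- 0L
  for (a in 0:(h / M - 1)) for (b in 0:(w / M - 1)) {
    lab <- integer(0)
    for (u in 0:(M - 1)) for (v in 0:(M - 1)) {
      i <- a * M + u; j <- b * M + v
      lab <- c(lab, oracle_region(i, h, M, s) * 3L + oracle_region(j, w, M, s))
    }
    for (uu in seq_along(lab)) for (vv in seq_along(lab)) {
      if (lab[uu] != lab[vv]) cnt <- cnt + 1L
    }
  }
  cnt
}

# Per-sample one-vs-rest metric counter, coded independently of
# class_metrics(): loops over samples and counts TP/TN/FP/FN directly.
oracle_class_metrics <- function(pred, truth, k) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    p <- pred[i] == k; t <- truth[i] == k
    if (p && t) tp <- tp + 1L
    else if (!p && !t) tn <- tn + 1L
    else if (p && !t) fp <- fp + 1L
    else fn <- fn + 1L
  }
  pre <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  c(Acc = (tp + tn) / length(pred),
    Pre = pre, Rec = rec,
    FS = if (pre + rec == 0) 0 else 2 * pre * rec / (pre + rec),
    Spe = if (tn + fp == 0) 0 else tn / (tn + fp))
}
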