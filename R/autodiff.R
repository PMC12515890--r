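# Reverse-mode automatic differentiation on a global tape.
#
# The network code builds a fresh tape per forward pass (define-by-run).
# Nodes are coarse-grained layer operations (convolution, window attention,
# normalization, ...) with hand-derived backward closures, so the tape stays
# short and the heavy lifting runs through BLAS. Handles are plain lists
# `list(id, val)`; id 0 marks a constant (no gradient tracked).

.ad <- new.env(parent = emptyenv())
.ad$nodes <- list()
.ad$n <- 0L
.ad$rec <- FALSE

#' @noRd
ad_reset <- function(record = TRUE) {
  .ad$nodes <- vector("list", 512L)
  .ad$n <- 0L
  .ad$rec <- isTRUE(record)
  .ad$param_ids <- list()
  .ad$grads <- NULL
  invisible(NULL)
}

ad_recording <- function() .ad$rec

# Create a tape node. `pids` are parent ids (0 for constants); `bw` maps the
# incoming gradient to a list of parent gradients aligned with `pids`.
ad_node <- function(val, pids = integer(), bw = NULL) {
  # force arguments before claiming a tape slot: nested op calls must
  # register their nodes first so ids stay topologically ordered
  force(val); force(pids); force(bw)
  if (!.ad$rec) return(list(id = 0L, val = val))
  n <- .ad$n + 1L
  if (n > length(.ad$nodes)) length(.ad$nodes) <- 2L * length(.ad$nodes)
  .ad$nodes[[n]] <- list(pids = as.integer(pids), bw = bw)
  .ad$n <- n
  list(id = n, val = val)
}

ad_const <- function(val) list(id = 0L, val = val)

ad_leaf <- function(val) ad_node(val)

# Leaf registered under a name so parameter gradients can be collected.
ad_param <- function(name, val) {
  nd <- ad_leaf(val)
  if (.ad$rec) .ad$param_ids[[name]] <- nd$id
  nd
}

as_ad <- function(x) if (is.list(x) && !is.null(x$id)) x else ad_const(x)

# Backpropagate from a root node. `seed` defaults to 1 (scalar roots);
# supply an array shaped like the root value otherwise.
ad_backward <- function(root, seed = NULL) {
  stopifnot(.ad$rec, root$id > 0L)
  n <- .ad$n
  grads <- vector("list", n)
  if (is.null(seed)) seed <- 1
  grads[[root$id]] <- seed
  for (id in seq.int(n, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    nd <- .ad$nodes[[id]]
    if (is.null(nd$bw)) next
    gs <- nd$bw(g)
    pids <- nd$pids
    for (k in seq_along(pids)) {
      p <- pids[k]
      if (p == 0L) next
      gk <- gs[[k]]
      if (is.null(gk)) next
      grads[[p]] <- if (is.null(grads[[p]])) gk else grads[[p]] + gk
    }
  }
  .ad$grads <- grads
  invisible(NULL)
}

ad_grad <- function(node) {
  if (node$id == 0L || is.null(.ad$grads)) return(NULL)
  .ad$grads[[node$id]]
}

# Named list of gradients matching a parameter list (zeros where unused).
ad_param_grads <- function(params) {
  out <- vector("list", length(params))
  names(out) <- names(params)
  for (nm in names(params)) {
    id <- .ad$param_ids[[nm]]
    g <- if (!is.null(id)) .ad$grads[[id]] else NULL
    if (is.null(g)) g <- array(0, dim = dim1(params[[nm]]))
    if (is.null(dim(params[[nm]]))) g <- as.vector(g)
    out[[nm]] <- g
  }
  out
}

dim1 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

## ---- elementwise and linear-algebra ops ------------------------------------

ad_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$val + b$val, c(a$id, b$id), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$val - b$val, c(a$id, b$id), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$val; bv <- b$val
  ad_node(av * bv, c(a$id, b$id), function(g) list(g * bv, g * av))
}

ad_scale <- function(a, s) {
  ad_node(a$val * s, a$id, function(g) list(g * s))
}

ad_matmul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$val; bv <- b$val
  ad_node(av %*% bv, c(a$id, b$id),
          function(g) list(tcrossprod(g, bv), crossprod(av, g)))
}

# Add a length-ncol vector to every row of a matrix.
ad_addrows <- function(x, b) {
  b <- as_ad(b)
  bv <- b$val
  val <- x$val
  val <- sweep(val, 2L, bv, "+")
  ad_node(val, c(x$id, b$id), function(g) list(g, colSums(g)))
}

ad_relu <- function(x) {
  xv <- x$val
  ad_node(pmax(xv, 0), x$id, function(g) list(g * (xv > 0)))
}

ad_gelu <- function(x) {
  xv <- x$val
  ad_node(xv * stats::pnorm(xv), x$id,
          function(g) list(g * (stats::pnorm(xv) + xv * stats::dnorm(xv))))
}

ad_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$val))
  ad_node(s, x$id, function(g) list(g * s * (1 - s)))
}

# Softmax over a numeric vector (returned as a vector).
ad_softmax <- function(z) {
  zv <- as.vector(z$val)
  m <- max(zv)
  e <- exp(zv - m)
  p <- e / sum(e)
  zd <- dim1(z$val)
  ad_node(p, z$id, function(g) {
    g <- as.vector(g)
    gz <- p * (g - sum(g * p))
    dim(gz) <- if (length(zd) > 1L) zd else NULL
    list(gz)
  })
}

# Free reshape (column-major layout is shared between equivalent dims).
ad_reshape <- function(x, newdim) {
  olddim <- dim1(x$val)
  v <- x$val
  dim(v) <- newdim
  ad_node(v, x$id, function(g) { dim(g) <- olddim; list(g) })
}

# y_flat[k] <- x_flat[idx[k]]; gradient scatter-adds back through idx.
ad_reindex <- function(x, idx, out_dim, in_dim = NULL) {
  xv <- x$val
  if (is.null(in_dim)) in_dim <- dim1(xv)
  v <- xv[idx]
  dim(v) <- out_dim
  ad_node(v, x$id, function(g) {
    dx <- numeric(prod(in_dim))
    rs <- rowsum(as.vector(g), group = idx)
    dx[as.integer(rownames(rs))] <- rs[, 1L]
    dim(dx) <- in_dim
    list(dx)
  })
}

# Row subset of a matrix (rows may repeat).
ad_rows <- function(x, ridx) {
  xv <- x$val
  nr <- nrow(xv)
  ad_node(xv[ridx, , drop = FALSE], x$id, function(g) {
    dx <- matrix(0, nr, ncol(xv))
    rs <- rowsum(g, group = ridx)
    dx[as.integer(rownames(rs)), ] <- rs
    list(dx)
  })
}

ad_cols <- function(x, cidx) {
  xv <- x$val
  ad_node(xv[, cidx, drop = FALSE], x$id, function(g) {
    dx <- matrix(0, nrow(xv), ncol(xv))
    dx[, cidx] <- g
    list(dx)
  })
}

# Column-bind matrices of equal row count.
ad_cbind <- function(...) {
  xs <- lapply(list(...), as_ad)
  ncols <- vapply(xs, function(x) ncol(x$val), 0L)
  val <- do.call(cbind, lapply(xs, `[[`, "val"))
  ends <- cumsum(ncols)
  starts <- c(1L, head(ends, -1L) + 1L)
  ad_node(val, vapply(xs, `[[`, 0L, "id"), function(g) {
    lapply(seq_along(xs), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

ad_mean <- function(x) {
  n <- length(x$val)
  ad_node(mean(x$val), x$id, function(g) list(array(g / n, dim = dim1(x$val))))
}

ad_sum <- function(x) {
  ad_node(sum(x$val), x$id, function(g) list(array(g, dim = dim1(x$val))))
}

## ---- normalization ---------------------------------------------------------

# Layer normalization over the columns of each row, with affine parameters.
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  gamma <- as_ad(gamma); beta <- as_ad(beta)
  xv <- x$val
  n <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gv <- gamma$val
  val <- sweep(xhat, 2L, gv, "*")
  val <- sweep(val, 2L, beta$val, "+")
  ad_node(val, c(x$id, gamma$id, beta$id), function(g) {
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    dxhat <- sweep(g, 2L, gv, "*")
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    dx <- inv * (dxhat - m1 - xhat * m2)
    list(dx, dgamma, dbeta)
  })
}

# Per-channel normalization of an (h, w, c) map over its spatial positions
# (statistics computed per sample, per channel).
ad_channelnorm <- function(x, gamma, beta, eps = 1e-5) {
  gamma <- as_ad(gamma); beta <- as_ad(beta)
  d <- dim(x$val)
  hw <- d[1L] * d[2L]; cc <- d[3L]
  if (hw == 1L) {
    # a single spatial position carries no distributional information to
    # normalize away; apply the affine transform only
    gv <- gamma$val
    xv <- x$val
    val <- sweep(sweep(xv, 3L, gv, "*"), 3L, beta$val, "+")
    return(ad_node(val, c(x$id, gamma$id, beta$id), function(g) {
      list(sweep(g, 3L, gv, "*"), as.vector(g * xv), as.vector(g))
    }))
  }
  xm <- x$val; dim(xm) <- c(hw, cc)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu, "-")
  v <- colMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv, "*")
  gv <- gamma$val
  val <- sweep(xhat, 2L, gv, "*")
  val <- sweep(val, 2L, beta$val, "+")
  dim(val) <- d
  ad_node(val, c(x$id, gamma$id, beta$id), function(g) {
    dim(g) <- c(hw, cc)
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    dxhat <- sweep(g, 2L, gv, "*")
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dx <- sweep(dxhat, 2L, m1, "-") - sweep(xhat, 2L, m2, "*")
    dx <- sweep(dx, 2L, inv, "*")
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}

## ---- convolution and pooling -----------------------------------------------

.conv_cache <- new.env(parent = emptyenv())

# Strided patch-index geometry for im2col; cached per shape.
conv_geom <- function(h, w, kh, kw, stride, pad) {
  key <- paste(h, w, kh, kw, stride, pad, sep = "_")
  g <- .conv_cache[[key]]
  if (!is.null(g)) return(g)
  h2 <- h + 2L * pad; w2 <- w + 2L * pad
  oh <- (h2 - kh) %/% stride + 1L
  ow <- (w2 - kw) %/% stride + 1L
  oi <- seq.int(1L, by = stride, length.out = oh)
  oj <- seq.int(1L, by = stride, length.out = ow)
  idx <- vector("list", kh * kw)
  o <- 0L
  for (kj in seq_len(kw)) for (ki in seq_len(kh)) {
    o <- o + 1L
    rows <- rep(oi + ki - 1L, times = ow)
    cols <- rep(oj + kj - 1L, each = oh)
    idx[[o]] <- rows + (cols - 1L) * h2
  }
  g <- list(h2 = h2, w2 = w2, oh = oh, ow = ow, idx = idx, noff = kh * kw)
  .conv_cache[[key]] <- g
  g
}

pad_to_matrix <- function(x, pad, fill = 0) {
  d <- dim(x)
  if (pad == 0L) {
    m <- x; dim(m) <- c(d[1L] * d[2L], d[3L])
    return(m)
  }
  h2 <- d[1L] + 2L * pad; w2 <- d[2L] + 2L * pad
  xp <- array(fill, c(h2, w2, d[3L]))
  xp[pad + seq_len(d[1L]), pad + seq_len(d[2L]), ] <- x
  dim(xp) <- c(h2 * w2, d[3L])
  xp
}

# 2-D convolution on an (h, w, cin) map. Weights are a
# (kh*kw*cin) x cout matrix, rows grouped by kernel offset then input channel.
ad_conv2d <- function(x, W, b, kh, kw, stride = 1L, pad = 0L) {
  W <- as_ad(W); b <- as_ad(b)
  xv <- x$val
  d <- dim(xv)
  cin <- d[3L]
  geo <- conv_geom(d[1L], d[2L], kh, kw, as.integer(stride), as.integer(pad))
  Mm <- pad_to_matrix(xv, as.integer(pad))
  nout <- geo$oh * geo$ow
  P <- matrix(0, nout, geo$noff * cin)
  for (o in seq_len(geo$noff)) {
    P[, ((o - 1L) * cin + 1L):(o * cin)] <- Mm[geo$idx[[o]], , drop = FALSE]
  }
  Wv <- W$val
  out <- P %*% Wv
  out <- sweep(out, 2L, b$val, "+")
  cout <- ncol(Wv)
  dim(out) <- c(geo$oh, geo$ow, cout)
  pad_i <- as.integer(pad)
  ad_node(out, c(x$id, W$id, b$id), function(g) {
    dim(g) <- c(nout, cout)
    dW <- crossprod(P, g)
    db <- colSums(g)
    dP <- tcrossprod(g, Wv)
    dMm <- matrix(0, nrow(Mm), cin)
    for (o in seq_len(geo$noff)) {
      blk <- dP[, ((o - 1L) * cin + 1L):(o * cin), drop = FALSE]
      dMm[geo$idx[[o]], ] <- dMm[geo$idx[[o]], , drop = FALSE] + blk
    }
    dim(dMm) <- c(geo$h2, geo$w2, cin)
    dx <- dMm[pad_i + seq_len(d[1L]), pad_i + seq_len(d[2L]), , drop = FALSE]
    dim(dx) <- d
    list(dx, dW, db)
  })
}

# Pointwise (1x1) convolution with optional spatial stride.
ad_conv1x1 <- function(x, W, b, stride = 1L) {
  d <- dim(x$val)
  xm <- ad_reshape(x, c(d[1L] * d[2L], d[3L]))
  if (stride > 1L) {
    keep_i <- seq.int(1L, d[1L], by = stride)
    keep_j <- seq.int(1L, d[2L], by = stride)
    ridx <- as.vector(outer(keep_i, (keep_j - 1L) * d[1L], "+"))
    xm <- ad_rows(xm, ridx)
    oh <- length(keep_i); ow <- length(keep_j)
  } else {
    oh <- d[1L]; ow <- d[2L]
  }
  y <- ad_addrows(ad_matmul(xm, as_ad(W)), b)
  ad_reshape(y, c(oh, ow, ncol1(W)))
}

ncol1 <- function(x) if (is.list(x)) ncol(x$val) else ncol(x)

# 3x3 stride-2 max pooling with padding 1 (stem pooling).
ad_maxpool <- function(x, k = 3L, stride = 2L, pad = 1L) {
  xv <- x$val
  d <- dim(xv)
  cc <- d[3L]
  geo <- conv_geom(d[1L], d[2L], k, k, stride, pad)
  Mm <- pad_to_matrix(xv, pad, fill = -Inf)
  cur <- Mm[geo$idx[[1L]], , drop = FALSE]
  arg <- matrix(1L, nrow(cur), cc)
  for (o in 2:geo$noff) {
    cand <- Mm[geo$idx[[o]], , drop = FALSE]
    upd <- cand > cur
    cur[upd] <- cand[upd]
    arg[upd] <- o
  }
  val <- cur
  dim(val) <- c(geo$oh, geo$ow, cc)
  ad_node(val, x$id, function(g) {
    dim(g) <- c(geo$oh * geo$ow, cc)
    dMm <- matrix(0, nrow(Mm), cc)
    for (o in seq_len(geo$noff)) {
      m <- which(arg == o)
      if (!length(m)) next
      rows <- ((m - 1L) %% nrow(arg)) + 1L
      cols <- ((m - 1L) %/% nrow(arg)) + 1L
      tgt <- cbind(geo$idx[[o]][rows], cols)
      dMm[tgt] <- dMm[tgt] + g[m]
    }
    dim(dMm) <- c(geo$h2, geo$w2, cc)
    dx <- dMm[pad + seq_len(d[1L]), pad + seq_len(d[2L]), , drop = FALSE]
    dim(dx) <- d
    list(dx)
  })
}

# Global average pooling of an (h, w, c) map to a 1 x c matrix.
ad_gap <- function(x) {
  d <- dim(x$val)
  hw <- d[1L] * d[2L]
  xm <- x$val; dim(xm) <- c(hw, d[3L])
  ad_node(matrix(colMeans(xm), 1L), x$id, function(g) {
    dx <- matrix(rep(as.vector(g) / hw, each = hw), hw, d[3L])
    dim(dx) <- d
    list(dx)
  })
}

# Per-channel scaling of an (h, w, c) map by a 1 x c weight matrix.
ad_scale_channels <- function(x, s) {
  d <- dim(x$val)
  sv <- as.vector(s$val)
  val <- sweep(x$val, 3L, sv, "*")
  xv <- x$val
  ad_node(val, c(x$id, s$id), function(g) {
    dx <- sweep(g, 3L, sv, "*")
    gm <- g * xv; dim(gm) <- c(d[1L] * d[2L], d[3L])
    list(dx, matrix(colSums(gm), 1L))
  })
}
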