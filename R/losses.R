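# Training losses: binary cross-entropy, focal loss, Gaussian-kernel
# correntropy loss, and the epoch-scheduled hybrid of the last two.
# The binary forms are exposed directly; the multiclass reduction treats the
# softmax vector against one-hot targets (per-class binary focal terms summed;
# correntropy averaged over one-hot coordinates).

.loss_eps <- 1e-7

#' Loss configuration
#'
#' @param alpha focal weighting factor in (0, 1); may be a per-class vector
#'   (e.g. inverse class frequencies) for imbalanced data.
#' @param gamma focal focusing parameter, >= 0.
#' @param sigma Gaussian kernel width of the correntropy loss, > 0.
#' @param switch_epoch epoch n up to which (inclusive) the focal branch is
#'   used; later epochs use the correntropy branch.
#' @param total_epochs total training epochs N (>= switch_epoch).
#' @param reduction `"mean"` or `"sum"` over a batch.
#' @param correntropy_on `"onehot"` averages the kernel loss over all one-hot
#'   coordinates; `"true_class"` evaluates it on the true-class probability
#'   only.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(alpha = 0.25, gamma = 2, sigma = 1,
                        switch_epoch = 30L, total_epochs = 100L,
                        reduction = c("mean", "sum"),
                        correntropy_on = c("onehot", "true_class")) {
  if (any(alpha <= 0) || any(alpha >= 1)) stop("alpha must lie in (0, 1)")
  if (gamma < 0) stop("gamma must be non-negative")
  if (sigma <= 0) stop("sigma must be positive")
  switch_epoch <- as.integer(switch_epoch)
  total_epochs <- as.integer(total_epochs)
  if (switch_epoch < 1L || switch_epoch > total_epochs) {
    stop("switch_epoch must satisfy 0 < n <= total_epochs")
  }
  structure(list(alpha = alpha, gamma = gamma, sigma = sigma,
                 switch_epoch = switch_epoch, total_epochs = total_epochs,
                 reduction = match.arg(reduction),
                 correntropy_on = match.arg(correntropy_on)),
            class = "loss_config")
}

check_binary_y <- function(y) {
  if (!all(y %in% c(0, 1))) stop("y must contain only 0/1 labels")
}

#' Binary cross-entropy
#'
#' `-y log(p) - (1 - y) log(1 - p)` with the prediction clamped to
#' `[1e-7, 1 - 1e-7]` to keep logarithms finite. Vectorised.
#'
#' @param p_hat predicted probability of class 1.
#' @param y true label, 0 or 1.
#' @export
cross_entropy <- function(p_hat, y) {
  check_binary_y(y)
  p <- clamp(p_hat, .loss_eps, 1 - .loss_eps)
  -y * log(p) - (1 - y) * log(1 - p)
}

#' Focal loss
#'
#' The class-weighted, modulation-damped cross-entropy
#' `-alpha (1-p)^gamma log(p)` for positives and
#' `-(1-alpha) p^gamma log(1-p)` for negatives. At `gamma = 0`,
#' `alpha = 0.5` it reduces to half the cross-entropy.
#'
#' @inheritParams cross_entropy
#' @param alpha weighting factor in (0, 1).
#' @param gamma focusing parameter, >= 0.
#' @export
focal_loss <- function(p_hat, y, alpha = 0.25, gamma = 2) {
  check_binary_y(y)
  if (gamma < 0) stop("gamma must be non-negative")
  p <- clamp(p_hat, .loss_eps, 1 - .loss_eps)
  y * (-alpha * (1 - p)^gamma * log(p)) +
    (1 - y) * (-(1 - alpha) * p^gamma * log(1 - p))
}

#' Correntropy loss
#'
#' `1 - exp(-(y - p)^2 / sigma^2)`: one minus a Gaussian kernel of the
#' prediction error. Bounded in `[0, 1)`, zero only at `p = y`, and
#' saturating (L0-like) for large errors, which makes it robust to outliers.
#'
#' @inheritParams cross_entropy
#' @param sigma kernel width, > 0.
#' @export
correntropy_loss <- function(p_hat, y, sigma = 1) {
  if (sigma <= 0) stop("sigma must be positive")
  1 - exp(-(y - p_hat)^2 / sigma^2)
}

#' Epoch-scheduled hybrid loss
#'
#' Uses the focal loss for epochs `t <= switch_epoch` (the pre-training phase
#' addressing class imbalance) and the correntropy loss afterwards
#' (`switch_epoch < t <= total_epochs`), matching the two branches exactly.
#'
#' @inheritParams cross_entropy
#' @param t current epoch (1-based).
#' @param cfg a [loss_config()].
#' @export
hybrid_loss <- function(p_hat, y, t, cfg = loss_config()) {
  if (t <= 0 || t > cfg$total_epochs) {
    stop("epoch t must satisfy 0 < t <= total_epochs")
  }
  if (t <= cfg$switch_epoch) {
    focal_loss(p_hat, y, alpha = cfg$alpha[1L], gamma = cfg$gamma)
  } else {
    correntropy_loss(p_hat, y, sigma = cfg$sigma)
  }
}

# Per-class alpha vector aligned with K classes.
alpha_vec <- function(cfg, K) {
  a <- cfg$alpha
  if (length(a) == 1L) rep(a, K) else {
    if (length(a) != K) stop("per-class alpha must have length K")
    a
  }
}

#' Multiclass hybrid loss on a softmax probability matrix
#'
#' One-hot reduction of the scheduled hybrid loss: per-class binary focal
#' terms are summed over classes (focal branch); the correntropy branch
#' averages the kernel loss over one-hot coordinates (or uses the true-class
#' probability only, per the configuration).
#'
#' @param prob `n x K` matrix of softmax probabilities (rows sum to 1).
#' @param labels integer vector of true classes, `0 .. K-1`.
#' @param t current epoch.
#' @param cfg a [loss_config()].
#' @return The batch-reduced loss (scalar).
#' @export
multiclass_hybrid_loss <- function(prob, labels, t, cfg = loss_config()) {
  if (is.vector(prob)) prob <- matrix(prob, nrow = 1L)
  K <- ncol(prob)
  if (any(labels < 0L | labels >= K)) stop("labels must lie in 0..K-1")
  per <- vapply(seq_len(nrow(prob)), function(i) {
    onehot_loss_value(prob[i, ], labels[i], t, cfg)
  }, 0)
  if (cfg$reduction == "mean") mean(per) else sum(per)
}

onehot_loss_value <- function(p, label, t, cfg) {
  K <- length(p)
  yk <- as.numeric(seq_len(K) == label + 1L)
  if (t <= cfg$switch_epoch) {
    a <- alpha_vec(cfg, K)
    pc <- clamp(p, .loss_eps, 1 - .loss_eps)
    sum(yk * (-a * (1 - pc)^cfg$gamma * log(pc)) +
          (1 - yk) * (-(1 - a) * pc^cfg$gamma * log(1 - pc)))
  } else if (cfg$correntropy_on == "onehot") {
    mean(1 - exp(-(yk - p)^2 / cfg$sigma^2))
  } else {
    1 - exp(-(1 - p[label + 1L])^2 / cfg$sigma^2)
  }
}

## ---- tape versions (training path) -----------------------------------------

# Hybrid loss as a tape op over a probability-vector node. The clamp passes
# gradients only inside the clamped interval.
ad_hybrid_loss <- function(p_node, label, t, cfg) {
  if (t <= 0 || t > cfg$total_epochs) {
    stop("epoch t must satisfy 0 < t <= total_epochs")
  }
  p <- as.vector(p_node$val)
  K <- length(p)
  yk <- as.numeric(seq_len(K) == label + 1L)
  if (t <= cfg$switch_epoch) {
    a <- alpha_vec(cfg, K)
    g <- cfg$gamma
    inside <- p > .loss_eps & p < 1 - .loss_eps
    pc <- clamp(p, .loss_eps, 1 - .loss_eps)
    val <- sum(yk * (-a * (1 - pc)^g * log(pc)) +
                 (1 - yk) * (-(1 - a) * pc^g * log(1 - pc)))
    # d/dp of each binary focal term
    dpos <- a * (g * (1 - pc)^pmax(g - 1, 0) * log(pc) - (1 - pc)^g / pc)
    dneg <- (1 - a) * (-g * pc^pmax(g - 1, 0) * log(1 - pc) + pc^g / (1 - pc))
    dp <- (yk * dpos + (1 - yk) * dneg) * inside
    ad_node(val, p_node$id, function(gr) list(gr * dp))
  } else {
    e <- yk - p
    ker <- exp(-e^2 / cfg$sigma^2)
    if (cfg$correntropy_on == "onehot") {
      val <- mean(1 - ker)
      dp <- -(2 * e / cfg$sigma^2) * ker / K
    } else {
      k0 <- label + 1L
      val <- 1 - ker[k0]
      dp <- numeric(K)
      dp[k0] <- -(2 * e[k0] / cfg$sigma^2) * ker[k0]
    }
    ad_node(val, p_node$id, function(gr) list(gr * dp))
  }
}
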