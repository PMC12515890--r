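# Shared fixtures: tiny synthetic datasets, model builders and weight
# surgery helpers. Everything is generated in code at test time.

micro_cfg <- function(K = 2L, ...) oct_config(K, preset = "micro", ...)

micro_model <- function(K = 2L, seed = 1L, ...) {
  oct_model(micro_cfg(K, ...), seed = seed)
}

rand_tensor <- function(S, seed = 1L) {
  octfusion:::with_seed(seed, array(stats::rnorm(S * S * 3), c(S, S, 3L)))
}

# Zero every parameter whose name matches `pattern`.
zero_weights <- function(model, pattern) {
  sel <- grep(pattern, names(model$params), value = TRUE)
  for (nm in sel) model$params[[nm]][] <- 0
  model
}

# Random attention weight set for a width-c, `heads`-head window-M layer.
rand_msa_weights <- function(cdim, heads, M, seed = 1L, sd = 0.3) {
  octfusion:::with_seed(seed, list(
    Wqkv = matrix(stats::rnorm(cdim * 3 * cdim, 0, sd), cdim, 3 * cdim),
    bqkv = stats::rnorm(3 * cdim, 0, 0.1),
    Wo = matrix(stats::rnorm(cdim * cdim, 0, sd), cdim, cdim),
    bo = stats::rnorm(cdim, 0, 0.1),
    rtab = matrix(stats::rnorm((2 * M - 1)^2 * heads, 0, sd),
                  (2 * M - 1)^2, heads)
  ))
}

# Write a small synthetic dataset and scan it back; splits are `n_train`
# and `n_val` per class, remainder to test.
make_dataset <- function(K = 2L, per_class = 6L, n_train = 4L, n_val = 2L,
                         image_size = 32L, seed = 1L, noise_sd = 8,
                         root = tempfile("ds")) {
  spec <- synthetic_spec(num_classes = K, images_per_class = per_class,
                         image_size = image_size, noise_sd = noise_sd,
                         seed = seed)
  imgs <- generate_dataset(spec)
  lab <- vapply(imgs, `[[`, 0L, "label")
  ord <- stats::ave(seq_along(lab), lab, FUN = seq_along)
  sp <- ifelse(ord <= n_train, "train",
               ifelse(ord <= n_train + n_val, "val", "test"))
  ids <- vapply(imgs, `[[`, "", "identifier")
  write_imagefolder(imgs, root, stats::setNames(sp, ids))
  list(spec = spec, images = imgs, root = root,
       index = scan_imagefolder(root))
}

# Central-difference gradient of fn at a few sampled coordinates of x.
fd_grad <- function(fn, x, eps = 1e-5, sample = 8L, seed = 99L) {
  idx <- octfusion:::with_seed(seed, sample(seq_along(x), min(sample, length(x))))
  g <- numeric(length(idx))
  for (k in seq_along(idx)) {
    xp <- x; xp[idx[k]] <- xp[idx[k]] + eps
    xm <- x; xm[idx[k]] <- xm[idx[k]] - eps
    g[k] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  list(idx = idx, grad = g)
}
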