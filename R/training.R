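# Training: Adam with decoupled weight decay, cosine learning-rate annealing
# between the configured endpoints, the epoch-scheduled hybrid loss, the
# adjacent-error convergence rule, and stratified k-fold cross-validation.

#' Training configuration
#'
#' Defaults follow the study protocol: Adam, batch size 128, initial learning
#' rate 1e-4 annealed (cosine) to 1e-6, weight decay 0.05 (decoupled), 100
#' epochs. Desk-scale runs override `epochs`, `batch_size` and the rates.
#'
#' @param epochs total training epochs N.
#' @param batch_size images per optimisation step.
#' @param lr_init,lr_min learning-rate endpoints of the cosine schedule.
#' @param weight_decay decoupled weight-decay coefficient.
#' @param decay_mode `"decoupled"` (applied directly to weights) or `"l2"`
#'   (added to gradients).
#' @param seed seed controlling weight init and batch shuffling.
#' @param verbose print one line per epoch.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 128L,
                         lr_init = 1e-4, lr_min = 1e-6, weight_decay = 0.05,
                         decay_mode = c("decoupled", "l2"),
                         seed = 1L, verbose = FALSE) {
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (lr_min > lr_init) stop("lr_min must not exceed lr_init")
  structure(list(epochs = epochs, batch_size = as.integer(batch_size),
                 lr_init = lr_init, lr_min = lr_min,
                 weight_decay = weight_decay,
                 decay_mode = match.arg(decay_mode),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

# Cosine annealing: lr_init at epoch 1, lr_min at epoch N.
cosine_lr <- function(t, N, lr_init, lr_min) {
  if (N <= 1L) return(lr_init)
  lr_min + 0.5 * (lr_init - lr_min) * (1 + cos(pi * (t - 1) / (N - 1)))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim1(p))),
       v = lapply(params, function(p) array(0, dim1(p))),
       t = 0L)
}

adam_step <- function(params, grads, st, lr, wd, decay_mode,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (decay_mode == "l2" && wd > 0) g <- g + wd * params[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    upd <- lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
    if (decay_mode == "decoupled" && wd > 0) {
      params[[nm]] <- params[[nm]] * (1 - lr * wd)
    }
    params[[nm]] <- params[[nm]] - upd
  }
  list(params = params, st = st)
}

# Forward + loss + backward for one image; returns loss, correctness and
# parameter gradients.
train_step_one <- function(model, x, label, t, loss_cfg) {
  out <- oct_forward(model, x, record = TRUE)
  pnode <- out$state$nodes$prob
  loss <- ad_hybrid_loss(pnode, label, t, loss_cfg)
  ad_backward(loss)
  g <- ad_param_grads(model$params)
  list(loss = loss$val, correct = (which.max(out$prob) - 1L) == label,
       grads = g)
}

load_split_tensors <- function(index, rows, size) {
  out <- vector("list", nrow(index))
  for (r in rows) out[[r]] <- preprocess(read_image(index$path[r]), size = size)
  out
}

#' Fit the dual-branch OCT classifier
#'
#' Runs the full training protocol on the `train` split of an image-folder
#' index, evaluating on the `val` split each epoch: Adam updates with the
#' epoch-scheduled hybrid loss (focal up to the switch epoch, correntropy
#' after), cosine learning-rate annealing, per-epoch logging, and retention
#' of the best-on-validation weights. Fully reproducible given the seed.
#'
#' @param index an [scan_imagefolder()] index with non-empty `train` and
#'   `val` splits.
#' @param model_cfg an [oct_config()] (or a prebuilt [oct_model()] to start
#'   from).
#' @param cfg a [train_config()].
#' @param loss_cfg a [loss_config()]; its `total_epochs` is aligned with
#'   `cfg$epochs`.
#' @param tensors optional list of preprocessed tensors aligned with index
#'   rows (images are decoded once and cached when omitted).
#' @param resume an earlier `oct_fit` to continue: training restarts at the
#'   next epoch with its weights and optimizer state, and the loss series
#'   continues without reset (identical to an uninterrupted run with the
#'   same seed and total epochs).
#' @return An object of class `oct_fit` with elements `model` (final
#'   weights), `best` (best-on-validation weights and epoch), `history`
#'   (per-epoch data frame: epoch, lr, loss branch, train/val loss and
#'   accuracy), `convergence` (first epoch satisfying the adjacent-error
#'   rule on validation loss) and the configurations used.
#' @seealso [predict.oct_fit()], [convergence_epoch()], [kfold_cv()]
#' @export
oct_fit <- function(index, model_cfg, cfg = train_config(),
                    loss_cfg = loss_config(), tensors = NULL,
                    resume = NULL) {
  stopifnot(inherits(cfg, "train_config"), inherits(loss_cfg, "loss_config"))
  tr_rows <- which(index$split == "train")
  va_rows <- which(index$split == "val")
  if (!length(tr_rows) || !length(va_rows)) {
    stop("index must contain non-empty 'train' and 'val' splits")
  }
  done <- 0L
  prev_hist <- NULL
  if (!is.null(resume)) {
    stopifnot(inherits(resume, "oct_fit"))
    model <- resume$model
    done <- nrow(resume$history)
    prev_hist <- resume$history
    if (cfg$epochs <= done) stop("resume: cfg$epochs must exceed the ",
                                 done, " epochs already completed")
  } else {
    model <- if (inherits(model_cfg, "oct_model")) model_cfg
             else oct_model(model_cfg, seed = cfg$seed)
  }
  mcfg <- model$cfg
  if (loss_cfg$total_epochs != cfg$epochs) loss_cfg$total_epochs <- cfg$epochs
  if (loss_cfg$switch_epoch > cfg$epochs) loss_cfg$switch_epoch <- cfg$epochs
  if (is.null(tensors)) {
    tensors <- load_split_tensors(index, c(tr_rows, va_rows), mcfg$image_size)
  }
  opt <- if (!is.null(resume)) resume$opt else adam_init(model$params)
  hist <- vector("list", cfg$epochs)
  if (done > 0L) for (i in seq_len(done)) hist[[i]] <- prev_hist[i, ]
  best <- if (!is.null(resume)) resume$best
          else list(val_loss = Inf, params = NULL, epoch = NA_integer_)
  for (t in seq.int(done + 1L, cfg$epochs)) {
    lr <- cosine_lr(t, cfg$epochs, cfg$lr_init, cfg$lr_min)
    batches <- batch_iterator(index, "train", cfg$batch_size,
                              shuffle_seed = stream_seed(cfg$seed, t),
                              size = mcfg$image_size, tensors = tensors)
    ep_loss <- 0; ep_n <- 0L; ep_correct <- 0L
    for (bi in seq_along(batches)) {
      b <- batches[[bi]]
      nb <- length(b$y)
      gsum <- NULL
      bloss <- 0
      for (j in seq_len(nb)) {
        stp <- train_step_one(model, b$x[, , , j], b$y[j], t, loss_cfg)
        if (!is.finite(stp$loss)) {
          stop(sprintf("non-finite loss at epoch %d, batch %d", t, bi))
        }
        bloss <- bloss + stp$loss
        ep_correct <- ep_correct + stp$correct
        gsum <- if (is.null(gsum)) stp$grads
                else Map(`+`, gsum, stp$grads)
      }
      if (loss_cfg$reduction == "mean") gsum <- lapply(gsum, `/`, nb)
      res <- adam_step(model$params, gsum, opt, lr, cfg$weight_decay,
                       cfg$decay_mode)
      model$params <- res$params
      opt <- res$st
      ep_loss <- ep_loss + bloss
      ep_n <- ep_n + nb
    }
    va <- eval_rows(model, index, va_rows, tensors, t, loss_cfg)
    branch <- if (t <= loss_cfg$switch_epoch) "focal" else "correntropy"
    hist[[t]] <- data.frame(epoch = t, lr = lr, loss_branch = branch,
                            train_loss = ep_loss / ep_n,
                            train_acc = ep_correct / ep_n,
                            val_loss = va$loss, val_acc = va$acc)
    if (va$loss < best$val_loss) {
      best <- list(val_loss = va$loss, params = model$params, epoch = t)
    }
    if (cfg$verbose) {
      message(sprintf(
        "epoch %3d [%s] lr %.2e train loss %.4f acc %.3f | val loss %.4f acc %.3f",
        t, branch, lr, ep_loss / ep_n, ep_correct / ep_n, va$loss, va$acc))
    }
  }
  history <- do.call(rbind, hist)
  rownames(history) <- NULL
  conv <- tryCatch(convergence_epoch(history$val_loss), error = function(e) NA)
  structure(list(model = model, best = best, history = history,
                 convergence = conv, train_cfg = cfg, loss_cfg = loss_cfg,
                 opt = opt, class_names = attr(index, "class_names")),
            class = "oct_fit")
}

eval_rows <- function(model, index, rows, tensors, t, loss_cfg) {
  loss <- 0; correct <- 0L
  preds <- integer(length(rows))
  for (k in seq_along(rows)) {
    r <- rows[k]
    out <- oct_forward(model, tensors[[r]], record = FALSE)
    loss <- loss + onehot_loss_value(out$prob, index$label[r], t, loss_cfg)
    preds[k] <- which.max(out$prob) - 1L
    correct <- correct + (preds[k] == index$label[r])
  }
  list(loss = loss / length(rows), acc = correct / length(rows),
       preds = preds)
}

#' First epoch at which training stabilises
#'
#' Applies the adjacent-error rule: the smallest epoch `t >= 2` whose
#' relative loss change `|L_t - L_(t-1)| / L_(t-1)` falls below the
#' threshold (default 0.5%).
#'
#' @param losses per-epoch loss series (validation loss by default in
#'   [oct_fit()]).
#' @param threshold relative-change threshold.
#' @return The epoch index, or `NA` if the rule is never satisfied.
#' @export
convergence_epoch <- function(losses, threshold = 0.005) {
  if (length(losses) < 2L) stop("need at least two epochs of losses")
  for (t in 2:length(losses)) {
    prev <- losses[t - 1L]
    if (prev <= 0) stop("undefined relative change: non-positive loss at epoch ",
                        t - 1L)
    if (abs(losses[t] - prev) / prev < threshold) return(t)
  }
  NA_integer_
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by class over the train+val records (the test split
#' is left untouched); each fold serves once as the validation/evaluation
#' split while the rest trains a fresh model. The reported value of each
#' metric is the mean over folds (with its standard deviation).
#'
#' @param index an [scan_imagefolder()] index.
#' @param model_cfg an [oct_config()].
#' @param cfg,loss_cfg training and loss configurations.
#' @param k number of folds (default 3).
#' @param seed fold-assignment seed.
#' @return A list with `folds` (per-fold accuracy and metric reports),
#'   `mean` and `sd` rows across folds.
#' @export
kfold_cv <- function(index, model_cfg, cfg = train_config(),
                     loss_cfg = loss_config(), k = 3L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  rows <- which(index$split != "test")
  labs <- index$label[rows]
  counts <- table(labs)
  if (any(counts < k)) {
    stop("every class needs at least k items for stratified folds")
  }
  fold <- integer(length(rows))
  with_seed(seed, {
    for (cl in unique(labs)) {
      sel <- which(labs == cl)
      fold[sel] <- sample(rep_len(seq_len(k), length(sel)))
    }
  })
  K <- length(attr(index, "class_names"))
  fold_out <- vector("list", k)
  for (f in seq_len(k)) {
    idx <- index
    idx$split[rows[fold != f]] <- "train"
    idx$split[rows[fold == f]] <- "val"
    fit <- oct_fit(idx, model_cfg, cfg, loss_cfg)
    ev <- eval_rows(fit$model, idx, which(idx$split == "val"),
                    load_split_tensors(idx, which(idx$split == "val"),
                                       fit$model$cfg$image_size),
                    cfg$epochs, loss_cfg)
    cm <- confusion_matrix(ev$preds, idx$label[idx$split == "val"], K,
                           attr(index, "class_names"))
    fold_out[[f]] <- list(accuracy = ev$acc, confusion = cm,
                          report = metrics_report(cm))
  }
  avg <- sapply(fold_out, function(fo) {
    c(accuracy = fo$accuracy,
      unlist(fo$report$average[c("Acc", "Pre", "Rec", "FS", "Spe")]))
  })
  list(folds = fold_out,
       mean = rowMeans(avg),
       sd = apply(avg, 1L, stats::sd))
}

#' @export
print.oct_fit <- function(x, ...) {
  h <- x$history
  last <- h[nrow(h), ]
  cat(sprintf("oct_fit: %d epochs (%s loss at end), %s parameters\n",
              nrow(h), last$loss_branch,
              format(n_params(x), big.mark = ",")))
  cat(sprintf("  final train acc %.3f, val acc %.3f; best val loss %.4f (epoch %d)\n",
              last$train_acc, last$val_acc, x$best$val_loss, x$best$epoch))
  cat(sprintf("  convergence epoch (0.5%% adjacent-error rule on val loss): %s\n",
              ifelse(is.na(x$convergence), "not reached", x$convergence)))
  invisible(x)
}

#' @export
summary.oct_fit <- function(object, ...) {
  print(object)
  cat("\nTraining history (last 5 epochs):\n")
  print(utils::tail(object$history, 5L), row.names = FALSE)
  invisible(object)
}

#' Plot training curves
#' @param x an `oct_fit`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.oct_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::abline(v = x$loss_cfg$switch_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' Trained weights of a fitted model
#' @param object an `oct_fit`.
#' @param best return the best-on-validation weights instead of the final ones.
#' @param ... unused.
#' @return Named list of parameter arrays.
#' @export
coef.oct_fit <- function(object, best = FALSE, ...) {
  if (best && !is.null(object$best$params)) object$best$params
  else object$model$params
}

#' Predict classes or probabilities for images
#'
#' @param object an `oct_fit`.
#' @param newdata an `oct_index` (all rows, or filtered via `split`), a
#'   single preprocessed tensor, or a list of `labeled_image`s.
#' @param split optional split name when `newdata` is an index.
#' @param type `"class"` (0-based predicted labels) or `"prob"`.
#' @param best use the best-on-validation weights.
#' @param ... unused.
#' @export
predict.oct_fit <- function(object, newdata, split = NULL,
                            type = c("class", "prob"), best = FALSE, ...) {
  type <- match.arg(type)
  model <- object$model
  if (best && !is.null(object$best$params)) model$params <- object$best$params
  S <- model$cfg$image_size
  tensors <- if (inherits(newdata, "oct_index")) {
    rows <- if (is.null(split)) seq_len(nrow(newdata))
            else which(newdata$split == split)
    if (!length(rows)) stop("no records in split: ", split)
    lapply(rows, function(r) preprocess(read_image(newdata$path[r]), size = S))
  } else if (is.array(newdata) && length(dim(newdata)) == 3L) {
    list(newdata)
  } else if (is.list(newdata)) {
    lapply(newdata, preprocess, size = S)
  } else {
    stop("unsupported newdata type")
  }
  probs <- t(vapply(tensors,
                    function(x) oct_forward(model, x)$prob,
                    numeric(model$cfg$num_classes)))
  colnames(probs) <- object$class_names %||%
    paste0("class", seq_len(ncol(probs)) - 1L)
  if (type == "prob") probs else max.col(probs) - 1L
}
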