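# Training loop mechanics: schedule endpoints, determinism, the loss-branch
# switch, the convergence rule and stratified cross-validation. Runs use the
# 32-pixel micro preset to stay fast.

test_that("the convergence rule applies the adjacent-error threshold", {
  expect_equal(convergence_epoch(c(1.00, 0.80, 0.798)), 3L)
  expect_true(is.na(convergence_epoch(c(1.0, 0.5, 0.25))))
  expect_equal(convergence_epoch(c(1.0, 1.0)), 2L)
  expect_error(convergence_epoch(c(1.0)), "two epochs")
  expect_error(convergence_epoch(c(0, 1)), "non-positive")
})

test_that("the cosine schedule hits both endpoints and never undershoots", {
  lrs <- vapply(1:100, octfusion:::cosine_lr, 0, N = 100, lr_init = 1e-4,
                lr_min = 1e-6)
  expect_equal(lrs[1], 1e-4)
  expect_equal(lrs[100], 1e-6)
  expect_true(all(lrs >= 1e-6))
  expect_true(all(diff(lrs) < 0))
  expect_equal(octfusion:::cosine_lr(1, 1, 1e-3, 1e-5), 1e-3)
  expect_error(train_config(lr_init = 1e-5, lr_min = 1e-4), "lr_min")
  expect_error(train_config(epochs = 0), "epochs")
})

test_that("identical seeds give bit-identical training logs", {
  ds <- make_dataset(K = 2, per_class = 6, n_train = 4, n_val = 2,
                     image_size = 32, seed = 3)
  run <- function() {
    oct_fit(ds$index, oct_config(2, preset = "micro"),
            train_config(epochs = 3, batch_size = 4, lr_init = 1e-3,
                         lr_min = 1e-4, seed = 11),
            loss_config(switch_epoch = 2, total_epochs = 3))
  }
  f1 <- run()
  f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  expect_equal(nrow(f1$history), 3L)
  # the logged loss branch switches exactly after the switch epoch
  expect_equal(f1$history$loss_branch, c("focal", "focal", "correntropy"))
  # and the training loss series actually changes when the seed does
  f3 <- oct_fit(ds$index, oct_config(2, preset = "micro"),
                train_config(epochs = 3, batch_size = 4, lr_init = 1e-3,
                             lr_min = 1e-4, seed = 12),
                loss_config(switch_epoch = 2, total_epochs = 3))
  expect_false(identical(f1$history$train_loss, f3$history$train_loss))
})

test_that("fit objects expose the standard modelling surface", {
  ds <- make_dataset(K = 2, per_class = 4, n_train = 3, n_val = 1,
                     image_size = 32, seed = 4)
  fit <- oct_fit(ds$index, oct_config(2, preset = "micro"),
                 train_config(epochs = 2, batch_size = 4, lr_init = 1e-3,
                              lr_min = 1e-4, seed = 5),
                 loss_config(switch_epoch = 1, total_epochs = 2))
  expect_s3_class(fit, "oct_fit")
  expect_output(print(fit), "oct_fit")
  expect_named(coef(fit)[1], names(fit$model$params)[1])
  pr <- predict(fit, ds$index, split = "val", type = "prob")
  expect_equal(dim(pr), c(2L, 2L))
  expect_equal(rowSums(pr), rep(1, 2), tolerance = 1e-9)
  cls <- predict(fit, ds$index, split = "val")
  expect_true(all(cls %in% 0:1))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  ev <- evaluate_model(fit, ds$index, split = "val")
  expect_true(ev$accuracy >= 0 && ev$accuracy <= 1)
  expect_equal(sum(ev$confusion), 2)
  expect_error(evaluate_model(fit, ds$index, split = "test"), "empty split")
})

test_that("training requires train and val splits", {
  ds <- make_dataset(K = 2, per_class = 3, n_train = 3, n_val = 0,
                     image_size = 32)
  expect_error(oct_fit(ds$index, oct_config(2, preset = "micro"),
                       train_config(epochs = 1, batch_size = 2)),
               "non-empty")
})

test_that("stratified folds have balanced sizes and classes", {
  ds <- make_dataset(K = 3, per_class = 10, n_train = 7, n_val = 3,
                     image_size = 32, seed = 6)
  rows <- which(ds$index$split != "test")
  labs <- ds$index$label[rows]
  fold <- integer(length(rows))
  octfusion:::with_seed(1, {
    for (cl in unique(labs)) {
      sel <- which(labs == cl)
      fold[sel] <- sample(rep_len(1:3, length(sel)))
    }
  })
  # each class splits 4/3/3 over the folds, so fold totals lie in 9..12
  expect_equal(sum(table(fold)), 30L)
  expect_true(all(table(fold) >= 9L & table(fold) <= 12L))
  for (f in 1:3) {
    per_class <- table(labs[fold == f])
    expect_true(all(per_class >= 3L & per_class <= 4L))
  }
  expect_error(kfold_cv(ds$index, oct_config(3, preset = "micro"), k = 1),
               "at least 2")
  small <- make_dataset(K = 2, per_class = 2, n_train = 2, n_val = 0,
                        image_size = 32, seed = 7)
  expect_error(kfold_cv(small$index, oct_config(2, preset = "micro"), k = 3),
               "at least k")
})

test_that("cross-validation aggregates fold accuracies arithmetically", {
  ds <- make_dataset(K = 2, per_class = 6, n_train = 4, n_val = 2,
                     image_size = 32, seed = 8)
  cv <- kfold_cv(ds$index, oct_config(2, preset = "micro"),
                 train_config(epochs = 2, batch_size = 4, lr_init = 1e-3,
                              lr_min = 1e-4, seed = 9),
                 loss_config(switch_epoch = 1, total_epochs = 2),
                 k = 3L, seed = 10)
  expect_length(cv$folds, 3L)
  accs <- vapply(cv$folds, `[[`, 0, "accuracy")
  expect_equal(unname(cv$mean["accuracy"]), mean(accs), tolerance = 1e-12)
  expect_equal(unname(cv$sd["accuracy"]), stats::sd(accs), tolerance = 1e-12)
  # each fold evaluation covered 4 held-out images
  expect_true(all(vapply(cv$folds, function(f) sum(f$confusion), 0) == 4))
})

test_that("resuming from a checkpoint continues the run without reset", {
  ds <- make_dataset(K = 2, per_class = 6, n_train = 4, n_val = 2,
                     image_size = 32, seed = 17)
  lcfg <- loss_config(switch_epoch = 2, total_epochs = 4)
  full <- oct_fit(ds$index, oct_config(2, preset = "micro"),
                  train_config(epochs = 4, batch_size = 4, lr_init = 1e-3,
                               lr_min = 1e-4, seed = 19), lcfg)
  half <- oct_fit(ds$index, oct_config(2, preset = "micro"),
                  train_config(epochs = 2, batch_size = 4, lr_init = 1e-3,
                               lr_min = 1e-4, seed = 19), lcfg)
  # note: the cosine schedule depends on total epochs, so resume with the
  # full-run training config
  res <- oct_fit(ds$index, oct_config(2, preset = "micro"),
                 train_config(epochs = 4, batch_size = 4, lr_init = 1e-3,
                              lr_min = 1e-4, seed = 19), lcfg, resume = half)
  expect_equal(nrow(res$history), 4L)
  expect_identical(res$history$train_loss[1:2], half$history$train_loss)
  expect_error(oct_fit(ds$index, oct_config(2, preset = "micro"),
                       train_config(epochs = 2, batch_size = 4, seed = 19),
                       lcfg, resume = half), "must exceed")
})

test_that("external weights load through the checked hook", {
  m <- micro_model(seed = 23)
  w <- m$params[["head.fc2.W"]]
  w[] <- 0.5
  m2 <- set_weights(m, list(head.fc2.W = w))
  expect_equal(m2$params[["head.fc2.W"]][1, 1], 0.5)
  expect_error(set_weights(m, list(nope = w)), "unknown parameter")
  expect_error(set_weights(m, list(head.fc2.W = w[1, , drop = FALSE])),
               "dimension mismatch")
})

test_that("a diverging run aborts with an epoch/batch diagnostic", {
  ds <- make_dataset(K = 2, per_class = 4, n_train = 3, n_val = 1,
                     image_size = 32, seed = 29)
  m <- micro_model(seed = 31)
  m$params[["head.fc1.W"]][1, 1] <- Inf
  expect_error(oct_fit(ds$index, m,
                       train_config(epochs = 1, batch_size = 4, seed = 31),
                       loss_config(switch_epoch = 1, total_epochs = 1)),
               "non-finite loss at epoch 1, batch 1")
})
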