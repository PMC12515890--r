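# Feature fusion module and full-model assembly: reshape conventions, CRB
# and ICAB algebra, the degenerate zero-weight identity, the multi-level
# chain and the classifier head.

test_that("token/map reshape follows the row-major convention and inverts exactly", {
  tok <- matrix(seq_len(4 * 3), 4, 3)
  m <- tokens_to_map(tok, 2, 2)
  expect_equal(m[1, 1, ], tok[1, ])
  expect_equal(m[1, 2, ], tok[2, ])
  expect_equal(m[2, 1, ], tok[3, ])
  expect_identical(map_to_tokens(m), tok)
  big <- octfusion:::with_seed(1, matrix(stats::rnorm(56 * 56 * 9), 56 * 56, 9))
  expect_equal(dim(tokens_to_map(big, 56, 56)), c(56L, 56L, 9L))
  expect_identical(map_to_tokens(tokens_to_map(big, 56, 56)), big)
  expect_error(tokens_to_map(tok, 3, 3), "does not match")
})

test_that("CRB with zero conv weights reduces to activation of the concat", {
  m <- zero_weights(micro_model(), "^ffm\\.s1\\.crb\\.")
  pget <- octfusion:::par_getter(m$params)
  octfusion:::ad_reset(FALSE)
  k_map <- octfusion:::with_seed(1, array(stats::rnorm(8 * 8 * 8), c(8, 8, 8)))
  d_map <- octfusion:::with_seed(2, array(stats::rnorm(8 * 8 * 8), c(8, 8, 8)))
  out <- octfusion:::fwd_crb(octfusion:::ad_const(k_map),
                             octfusion:::ad_const(d_map), "ffm.s1", pget)
  cat_in <- array(c(k_map, d_map), c(8, 8, 16))
  expect_equal(out$val, pmax(cat_in, 0))
  # concatenation order matters
  m2 <- micro_model(seed = 5)
  pget2 <- octfusion:::par_getter(m2$params)
  octfusion:::ad_reset(FALSE)
  a <- octfusion:::fwd_crb(octfusion:::ad_const(k_map),
                           octfusion:::ad_const(d_map), "ffm.s1", pget2)
  octfusion:::ad_reset(FALSE)
  b <- octfusion:::fwd_crb(octfusion:::ad_const(d_map),
                           octfusion:::ad_const(k_map), "ffm.s1", pget2)
  expect_gt(max(abs(a$val - b$val)), 1e-6)
})

test_that("ICAB saturates to identity or null with extreme fc bias", {
  m <- zero_weights(micro_model(), "^ffm\\.s1\\.icab\\.fc\\.W")
  f <- octfusion:::with_seed(3, array(stats::rnorm(8 * 8 * 16), c(8, 8, 16)))
  for (bias in c(30, -30)) {
    m$params[["ffm.s1.icab.fc.b"]][] <- bias
    pget <- octfusion:::par_getter(m$params)
    octfusion:::ad_reset(FALSE)
    out <- octfusion:::fwd_icab(octfusion:::ad_const(f), "ffm.s1", pget)
    if (bias > 0) expect_equal(out$val, f, tolerance = 1e-9)
    else expect_lt(max(abs(out$val)), 1e-9)
  }
  # GAP equals the brute-force spatial mean
  octfusion:::ad_reset(FALSE)
  g <- octfusion:::ad_gap(octfusion:::ad_const(f))
  expect_equal(as.vector(g$val), apply(f, 3, mean), tolerance = 1e-12)
  cf <- array(rep(1:16, each = 64), c(8, 8, 16))
  octfusion:::ad_reset(FALSE)
  expect_equal(as.vector(octfusion:::ad_gap(octfusion:::ad_const(cf))$val),
               as.numeric(1:16))
})

test_that("a zero-weight FFM feeds back exactly nothing", {
  m <- zero_weights(micro_model(), "^ffm\\.s1\\.")
  pget <- octfusion:::par_getter(m$params)
  octfusion:::ad_reset(FALSE)
  k <- octfusion:::with_seed(4, matrix(stats::rnorm(64 * 8), 64, 8))
  d <- octfusion:::with_seed(5, array(stats::rnorm(8 * 8 * 16), c(8, 8, 16)))
  step <- octfusion:::fwd_ffm_step(octfusion:::ad_const(k),
                                   octfusion:::ad_const(d), NULL, 1L,
                                   m$cfg, pget)
  expect_identical(step$k_back$val, k)
  expect_identical(step$d_back$val, d)
})

test_that("channel split halves concatenate back to the fused map exactly", {
  m <- micro_model(seed = 2)
  pget <- octfusion:::par_getter(m$params)
  octfusion:::ad_reset(FALSE)
  f <- octfusion:::with_seed(6, array(stats::rnorm(8 * 8 * 16), c(8, 8, 16)))
  k_half <- octfusion:::ad_channel_slice(octfusion:::ad_const(f), 1:8)
  d_half <- octfusion:::ad_channel_slice(octfusion:::ad_const(f), 9:16)
  expect_identical(array(c(k_half$val, d_half$val), dim(f)), f)
})

test_that("the multi-level chain is live and shape-matched", {
  m <- micro_model(seed = 3)
  pget <- octfusion:::par_getter(m$params)
  octfusion:::ad_reset(FALSE)
  k2 <- octfusion:::with_seed(7, matrix(stats::rnorm(16 * 16), 16, 16))
  d2 <- octfusion:::with_seed(8, array(stats::rnorm(4 * 4 * 32), c(4, 4, 32)))
  prev <- octfusion:::with_seed(9, array(stats::rnorm(8 * 8 * 16), c(8, 8, 16)))
  with_prev <- octfusion:::fwd_ffm_step(octfusion:::ad_const(k2),
                                        octfusion:::ad_const(d2),
                                        octfusion:::ad_const(prev), 2L,
                                        m$cfg, pget)
  expect_equal(dim(with_prev$fused$val), c(4L, 4L, 32L))
  octfusion:::ad_reset(FALSE)
  without <- octfusion:::fwd_ffm_step(octfusion:::ad_const(k2),
                                      octfusion:::ad_const(d2), NULL, 2L,
                                      m$cfg, pget)
  expect_gt(max(abs(with_prev$fused$val - without$fused$val)), 1e-6)
})

test_that("the classifier head lives on the probability simplex", {
  m <- micro_model(K = 3, seed = 4)
  pget <- octfusion:::par_getter(m$params)
  octfusion:::ad_reset(FALSE)
  f4 <- octfusion:::with_seed(10, array(stats::rnorm(128), c(1, 1, 128)))
  head <- octfusion:::fwd_classifier(octfusion:::ad_const(f4), m$cfg, pget)
  p <- as.vector(head$prob$val)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p > 0 & p < 1))
  # zero final layer -> uniform probabilities
  mz <- zero_weights(m, "^head\\.fc2\\.")
  pgetz <- octfusion:::par_getter(mz$params)
  octfusion:::ad_reset(FALSE)
  pz <- octfusion:::fwd_classifier(octfusion:::ad_const(f4), mz$cfg, pgetz)$prob$val
  expect_equal(as.vector(pz), rep(1 / 3, 3), tolerance = 1e-12)
  # softmax shift invariance of the argmax
  octfusion:::ad_reset(FALSE)
  lg <- head$logits$val
  e <- exp(lg + 5 - max(lg + 5)); shifted <- e / sum(e)
  expect_equal(which.max(shifted), which.max(p))
})

test_that("the full forward pass obeys the shape ledger and is deterministic", {
  cfg <- oct_config(3, preset = "tiny")
  m <- oct_model(cfg, seed = 1)
  x <- rand_tensor(64, 11)
  out1 <- oct_forward(m, x)
  out2 <- oct_forward(m, x)
  expect_identical(out1$prob, out2$prob)
  expect_length(out1$prob, 3L)
  expect_equal(sum(out1$prob), 1, tolerance = 1e-9)
  got <- t(vapply(out1$state$fused, dim, integer(3)))
  expect_equal(got[, 1], c(16L, 8L, 4L, 2L))
  expect_equal(got[, 3], 2L * 16L * c(1L, 2L, 4L, 8L))
  expect_error(oct_forward(m, rand_tensor(32, 1)), "64x64x3")
})

test_that("a real forward at the default 224-pixel scale matches the ledger", {
  cfg <- oct_config(4, preset = "default")
  m <- oct_model(cfg, seed = 1)
  out <- oct_forward(m, rand_tensor(224, 20))
  got <- t(vapply(out$state$fused, dim, integer(3)))
  expect_equal(got[, 1], c(56L, 28L, 14L, 7L))
  expect_equal(got[, 3], 2L * 96L * c(1L, 2L, 4L, 8L))
  expect_equal(sum(out$prob), 1, tolerance = 1e-9)
  rm(m, out); gc(verbose = FALSE)
})

test_that("every parameter group receives gradient in the tiny assembly", {
  cfg <- oct_config(2, preset = "tiny")
  m <- oct_model(cfg, seed = 2)
  out <- oct_forward(m, rand_tensor(64, 12), record = TRUE)
  loss <- octfusion:::ad_hybrid_loss(out$state$nodes$prob, 0L, 1L,
                                     loss_config())
  octfusion:::ad_backward(loss)
  g <- octfusion:::ad_param_grads(m$params)
  dead <- names(g)[vapply(g, function(x) all(x == 0), TRUE)]
  expect_identical(dead, character(0))
})

test_that("disabling the multi-level chain changes the prediction", {
  cfg_on <- oct_config(2, preset = "micro")
  cfg_off <- oct_config(2, preset = "micro", fusion_forward = "none")
  m_on <- oct_model(cfg_on, seed = 6)
  m_off <- m_on
  m_off$cfg <- cfg_off
  m_off$params <- m_on$params[setdiff(names(m_on$params),
                                      grep("\\.prev\\.", names(m_on$params),
                                           value = TRUE))]
  x <- rand_tensor(32, 13)
  p_on <- oct_forward(m_on, x)$prob
  p_off <- oct_forward(m_off, x)$prob
  expect_gt(max(abs(p_on - p_off)), 1e-9)
})
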