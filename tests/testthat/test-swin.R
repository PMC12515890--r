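# Shifted-window attention branch: patch partition/merging arithmetic,
# cyclic-shift mask construction, and equivalence of the windowed attention
# with brute-force oracles.

test_that("patch partition produces the token-grid arithmetic and locality", {
  cfg <- oct_config(2, preset = "tiny")  # patch 4, C = 16
  m <- oct_model(cfg, seed = 1)
  pget <- octfusion:::par_getter(m$params)
  octfusion:::ad_reset(FALSE)
  x <- rand_tensor(64, 1)
  tok <- octfusion:::fwd_patch_partition(octfusion:::ad_const(x), cfg, pget)
  expect_equal(dim(tok$val), c(256L, 16L))
  # permuting two whole input patches permutes exactly those two tokens
  x2 <- x
  x2[1:4, 1:4, ] <- x[1:4, 5:8, ]
  x2[1:4, 5:8, ] <- x[1:4, 1:4, ]
  octfusion:::ad_reset(FALSE)
  tok2 <- octfusion:::fwd_patch_partition(octfusion:::ad_const(x2), cfg, pget)
  expect_equal(tok2$val[1, ], tok$val[2, ])
  expect_equal(tok2$val[2, ], tok$val[1, ])
  expect_equal(tok2$val[-(1:2), ], tok$val[-(1:2), ])
  expect_error(octfusion:::fwd_patch_partition(
    octfusion:::ad_const(rand_tensor(30, 1)), cfg, pget), "divisible")
})

test_that("patch merging halves the grid and doubles the width", {
  m <- micro_model()
  pget <- octfusion:::par_getter(m$params)
  octfusion:::ad_reset(FALSE)
  tok <- octfusion:::with_seed(3, matrix(stats::rnorm(64 * 8), 64, 8))
  merged <- octfusion:::fwd_patch_merging(octfusion:::ad_const(tok), 8L, 8L,
                                          "swin.m2", pget)
  expect_equal(dim(merged$val), c(16L, 16L))
  # smallest case: 2x2 grid of c tokens -> a single 2c token
  m22 <- octfusion:::fwd_patch_merging(
    octfusion:::ad_const(tok[1:4, , drop = FALSE]), 2L, 2L, "swin.m2", pget)
  expect_equal(dim(m22$val), c(1L, 16L))
  # constant tokens stay constant across the merged grid
  ctok <- matrix(rep(seq_len(8), each = 64), 64, 8)
  mc <- octfusion:::fwd_patch_merging(octfusion:::ad_const(ctok), 8L, 8L,
                                      "swin.m2", pget)
  expect_lt(max(abs(sweep(mc$val, 2L, mc$val[1, ]))), 1e-9)
  expect_error(octfusion:::fwd_patch_merging(
    octfusion:::ad_const(tok[1:24, ]), 3L, 8L, "swin.m2", pget), "even")
})

test_that("shift masks reproduce the region decomposition", {
  # no shift: every entry zero
  m0 <- build_shift_mask(8, 8, 4, 0)
  expect_length(m0, 4)
  expect_true(all(vapply(m0, function(x) all(x == 0), TRUE)))
  # 8x8, M=4, s=2: the wrap-around corner window spans 4 distinct regions
  m2 <- build_shift_mask(8, 8, 4, 2)
  nlab <- vapply(m2, function(mask) {
    # number of regions = number of distinct rows of the 0/-LARGE pattern
    nrow(unique(mask))
  }, 0L)
  expect_equal(sort(nlab), c(1L, 2L, 2L, 4L))
  expect_true(all(unlist(m2) %in% c(0, -1e4)))
  expect_error(build_shift_mask(8, 8, 4, 4), "shift")
  expect_error(build_shift_mask(6, 6, 4, 1), "divisible")
})

test_that("masked entries match brute-force region enumeration on all geometries", {
  for (M in c(2L, 4L)) {
    for (h in seq.int(M, 8L, by = M)) for (w in seq.int(M, 8L, by = M)) {
      for (s in unique(c(0L, 1L, M %/% 2L))) {
        masks <- build_shift_mask(h, w, M, s)
        expect_equal(sum(unlist(masks) != 0), oracle_mask_count(h, w, M, s),
                     info = sprintf("h=%d w=%d M=%d s=%d", h, w, M, s))
      }
    }
  }
})

test_that("masked-row softmax normalizes over unmasked entries only", {
  masks <- build_shift_mask(8, 8, 4, 2)
  mask <- masks[[4]]  # wrap-around corner
  S <- octfusion:::with_seed(5, matrix(stats::rnorm(256), 16, 16)) + mask
  P <- exp(S - apply(S, 1, max))
  P <- P / rowSums(P)
  for (i in 1:16) {
    un <- mask[i, ] == 0
    expect_equal(sum(P[i, un]), 1, tolerance = 1e-9)
    expect_true(all(P[i, !un] < 1e-12))
  }
})

test_that("single unshifted window equals global self-attention", {
  cdim <- 6L; heads <- 2L; M <- 4L
  wts <- rand_msa_weights(cdim, heads, M, seed = 8)
  x <- octfusion:::with_seed(9, matrix(stats::rnorm(16 * cdim), 16, cdim))
  got <- window_msa(x, 4, 4, M, 0, heads, wts)
  # brute-force global attention with the same bias table
  want <- oracle_window_attention(x, 4, 4, M, 0, heads, wts)
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("shifted-window attention matches the region-wise oracle on all geometries", {
  for (M in c(2L, 4L)) {
    heads <- 2L
    cdim <- 4L
    for (h in seq.int(M, 8L, by = M)) for (w in seq.int(M, 8L, by = M)) {
      for (s in unique(c(0L, 1L, M %/% 2L))) {
        wts <- rand_msa_weights(cdim, heads, M, seed = h * 100L + w * 10L + s)
        x <- octfusion:::with_seed(h + w + s,
                                   matrix(stats::rnorm(h * w * cdim), h * w, cdim))
        got <- window_msa(x, h, w, M, s, heads, wts)
        want <- oracle_window_attention(x, h, w, M, s, heads, wts)
        expect_lt(max(abs(got - want)), 1e-5)
      }
    }
  }
})

test_that("zero value/output projections silence the attention path", {
  cdim <- 4L; wts <- rand_msa_weights(cdim, 2L, 2L, seed = 3)
  wts$Wo[] <- 0; wts$bo[] <- 0
  x <- octfusion:::with_seed(4, matrix(stats::rnorm(16 * cdim), 16, cdim))
  expect_equal(max(abs(window_msa(x, 4, 4, 2, 1, 2, wts))), 0)
})

test_that("a zero-weight transformer stage is an exact residual pass-through", {
  m <- micro_model()
  m <- zero_weights(m, "^swin\\.s1\\.")
  pget <- octfusion:::par_getter(m$params)
  octfusion:::ad_reset(FALSE)
  tok <- octfusion:::with_seed(6, matrix(stats::rnorm(64 * 8), 64, 8))
  out <- octfusion:::fwd_swin_stage(octfusion:::ad_const(tok), 8L, 8L, 1L,
                                    m$cfg, pget)
  expect_identical(out$val, tok)
})

test_that("stage outputs stay finite over random inputs", {
  m <- micro_model(seed = 2)
  pget <- octfusion:::par_getter(m$params)
  for (s in 1:20) {
    octfusion:::ad_reset(FALSE)
    tok <- octfusion:::with_seed(s, matrix(stats::rnorm(64 * 8, 0, 3), 64, 8))
    out <- octfusion:::fwd_swin_stage(octfusion:::ad_const(tok), 8L, 8L, 1L,
                                      m$cfg, pget)
    expect_true(all(is.finite(out$val)))
  }
})

test_that("stage geometry follows the C,2C,4C,8C ledger", {
  cfg <- oct_config(2, preset = "default")
  sh <- model_shapes(cfg)
  expect_equal(sh$grid, c(56L, 28L, 14L, 7L))
  expect_equal(sh$swin_width, 96L * c(1L, 2L, 4L, 8L))
  expect_error(oct_config(2, depths = c(2, 3, 6, 2)), "even")
})
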