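lut_cache <- new.env()
get_lut <- function(name) {
  if (is.null(lut_cache[[name]]))
    lut_cache[[name]] <- build_lookup(example_protocol(name))
  lut_cache[[name]]
}

test_that("UNI is strictly decreasing in T1 on every branch column", {
  for (nm in c("mp2rageme", "mp2rage")) {
    lut <- get_lut(nm)
    for (j in seq_along(lut$b1_grid)) {
      br <- lut$branch[, j]
      expect_true(all(diff(lut$uni[br[1]:br[2], j]) < 0))
      expect_gte(br[2] - br[1] + 1, length(lut$t1_grid) / 2)
    }
  }
})

test_that("a single-column table reduces to the classic 1-D lookup", {
  p <- example_protocol("mp2rage")
  lut1 <- build_lookup(p, b1_grid = 1.0)
  expect_equal(dim(lut1$uni), c(length(lut1$t1_grid), 1L))
  u <- simulate_uni(p, 1.85, 1, 1)
  res <- lookup_t1(lut1, as.numeric(u), 1)
  expect_lt(abs(res$t1 - 1.85), 0.001)
  expect_true(res$valid)
})

test_that("encode-then-decode is the identity to 1 ms on the branch", {
  for (nm in c("mp2rageme", "mp2rage")) {
    p <- example_protocol(nm)
    lut <- get_lut(nm)
    set.seed(7)
    t1s <- sample(seq(0.5, 5, by = 0.001), 250)
    b1s <- sample(seq(0.65, 1.35, by = 0.01), 250, replace = TRUE)
    u <- simulate_uni(p, t1s, b1s, 1)
    res <- lookup_t1(lut, as.numeric(u), b1s)
    expect_true(all(res$valid))
    expect_lt(max(abs(res$t1 - t1s)), 0.001)
  }
})

test_that("apparent T1 bias vanishes when decoding at the encoding B1", {
  p <- example_protocol("mp2rageme")
  lut <- get_lut("mp2rageme")
  for (b1 in c(0.8, 1.0, 1.2)) {
    u <- simulate_uni(p, c(0.9, 1.15, 1.85, 3.2), b1, 1)
    res <- lookup_t1(lut, as.numeric(u), b1)
    expect_lt(max(abs(res$t1 - c(0.9, 1.15, 1.85, 3.2))), 0.001)
  }
})

test_that("decoding a B1-miscalibrated white-matter signal biases T1 as expected", {
  p <- example_protocol("mp2rageme")
  lut <- get_lut("mp2rageme")
  # encoded at B1 = 1.2, decoded at the true field: unbiased
  u <- as.numeric(simulate_uni(p, 1.15, 1.2, 1))
  right <- lookup_t1(lut, u, 1.2)
  expect_lt(abs(right$t1 - 1.15), 0.001)
  # decoded at nominal: biased away from the truth but on the branch
  wrong <- lookup_t1(lut, u, 1.0)
  expect_true(wrong$valid)
  expect_gt(abs(wrong$t1 - 1.15), 0.05)
})

test_that("volume decoding recovers a noiseless forward-simulated volume", {
  p <- example_protocol("mp2rageme")
  lut <- get_lut("mp2rageme")
  set.seed(3)
  dims <- c(6, 5, 4)
  t1_vol <- array(runif(prod(dims), 0.6, 4.5), dims)
  b1_vol <- array(runif(prod(dims), 0.8, 1.2), dims)
  uni_vol <- array(as.numeric(simulate_uni(p, t1_vol, b1_vol, 1)), dims)
  res <- t1_from_uni(uni_vol, b1_vol, lut)
  expect_equal(dim(res$t1_map), dims)
  expect_true(all(res$validity_mask))
  expect_lt(max(abs(res$t1_map - t1_vol)), 0.002)
})

test_that("out-of-branch intensities clamp to branch ends and clear validity", {
  p <- example_protocol("mp2rageme")
  lut <- build_lookup(p, t1_grid = seq(0.5, 5, by = 0.001), b1_grid = 1)
  u_hi <- lut$uni[lut$branch[1, 1], 1]   # branch-end intensities
  u_lo <- lut$uni[lut$branch[2, 1], 1]
  res <- lookup_t1(lut, c(u_hi + 0.01, u_lo - 0.01), 1)
  expect_false(any(res$valid))
  expect_equal(res$t1[1], lut$t1_grid[lut$branch[1, 1]])
  expect_equal(res$t1[2], lut$t1_grid[lut$branch[2, 1]])
  # on-branch values right at the ends remain valid
  res2 <- lookup_t1(lut, c(u_hi, u_lo), 1)
  expect_true(all(res2$valid))
})

test_that("B1 values outside the table are clamped with a warning", {
  lut <- get_lut("mp2rageme")
  u <- as.numeric(simulate_uni(example_protocol("mp2rageme"), 1.15, 1, 1))
  expect_warning(res <- lookup_t1(lut, u, 2.0), "clamped")
  expect_equal(res$b1_clamped, 1L)
})

test_that("missing B1 map triggers the uncorrected-mode warning", {
  lut <- get_lut("mp2rageme")
  u <- array(as.numeric(simulate_uni(example_protocol("mp2rageme"),
                                     c(1.0, 1.5), 1, 1)), c(2, 1, 1))
  expect_warning(res <- t1_from_uni(u, NULL, lut), "uncorrected")
  expect_lt(max(abs(res$t1_map - c(1.0, 1.5))), 0.001)
})

test_that("transmit-field resampling preserves constants and smooth ramps", {
  const <- array(1.07, c(4, 4, 4))
  up <- resample_b1(const, c(12, 12, 12))
  expect_equal(dim(up), c(12L, 12L, 12L))
  expect_equal(as.numeric(up), rep(1.07, 12^3))

  # linear ramp along x survives trilinear upsampling in the interior
  ramp <- array(rep(seq(0.8, 1.2, length.out = 8), 8 * 8), c(8, 8, 8))
  up <- resample_b1(ramp, c(24, 24, 24), smooth = FALSE)
  interior <- up[4:21, 12, 12]
  expect_lt(max(abs(diff(interior) - mean(diff(interior)))), 1e-9)
  expect_true(all(up >= 0.8 - 1e-9 & up <= 1.2 + 1e-9))
})
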