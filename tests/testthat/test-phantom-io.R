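p_me <- example_protocol("mp2rageme")

test_that("the same seed reproduces volumes bit for bit; seeds differ otherwise", {
  cfg <- phantom_config(grid_shape = c(16, 16, 16), snr = 20, seed = 9L)
  a <- generate_phantom(cfg, p_me)
  b <- generate_phantom(cfg, p_me)
  expect_identical(a$inv1_mag, b$inv1_mag)
  expect_identical(a$inv2_mag, b$inv2_mag)
  expect_identical(a$inv2_phase, b$inv2_phase)
  cfg2 <- phantom_config(grid_shape = c(16, 16, 16), snr = 20, seed = 10L)
  c <- generate_phantom(cfg2, p_me)
  expect_false(identical(a$inv1_mag, c$inv1_mag))
})

test_that("phantom generation does not disturb the session RNG", {
  set.seed(1234)
  before <- .Random.seed
  invisible(generate_phantom(phantom_config(grid_shape = c(16, 16, 16), seed = 2L), p_me))
  expect_identical(.Random.seed, before)
})

test_that("noiseless volumes round-trip through the full quantification", {
  cfg <- phantom_config(grid_shape = c(24, 24, 24), snr = Inf, seed = 1L)
  vols <- generate_phantom(cfg, p_me)
  expect_equal(vols$noise_sd, 0)
  lut <- build_lookup(p_me)
  z1 <- vols$inv1_mag * exp(1i * vols$inv1_phase)
  z2 <- array(vols$inv2_mag[, , , 1], dim(vols$inv1_mag)) *
    exp(1i * array(vols$inv2_phase[, , , 1], dim(vols$inv1_mag)))
  uni <- Re(z1 * Conj(z2)) / (Mod(z1)^2 + Mod(z2)^2)
  uni[!is.finite(uni)] <- 0
  res <- t1_from_uni(array(uni, dim(z1)), vols$b1, lut)
  tab_t1 <- roi_medians(res$t1_map, vols$truth$labels, cfg$tissue_table)
  fit <- t2star_fit(vols$inv2_mag, vols$tes)
  tab_t2 <- roi_medians(fit$t2star, vols$truth$labels, cfg$tissue_table)
  m <- merge(merge(tab_t1, tab_t2, by = c("label", "name"),
                   suffixes = c("_t1", "_t2")),
             cfg$tissue_table, by = c("label", "name"))
  m <- m[m$n_t1 > 0, ]
  expect_gte(nrow(m), 5)
  expect_lt(max(abs(m$median_t1 - m$t1)), 0.002)        # within quantization
  expect_lt(max(abs(m$median_t2 - m$t2star) / m$t2star), 1e-6)
})

test_that("nonpositive SNR warns and disables noise", {
  expect_warning(
    v <- generate_phantom(phantom_config(grid_shape = c(16, 16, 16), snr = 0,
                                         seed = 1L), p_me),
    "noiseless")
  expect_equal(v$noise_sd, 0)
})

test_that("transmit-field decimation emulates a low-resolution acquired map", {
  cfg <- phantom_config(grid_shape = c(24, 24, 24), snr = Inf, seed = 1L,
                        b1_decimate = 3L)
  vols <- generate_phantom(cfg, p_me)
  expect_equal(dim(vols$b1), c(8L, 8L, 8L))
  up <- resample_b1(vols$b1, c(24, 24, 24))
  expect_true(all(up >= cfg$b1_range[1] - 0.02 & up <= cfg$b1_range[2] + 0.02))
})

test_that("NIfTI round trip preserves data and voxel geometry", {
  set.seed(6)
  vol <- array(rnorm(10 * 12 * 8), c(10, 12, 8))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f, voxel_size = 0.64)
  back <- read_volume(f)
  expect_equal(as.numeric(back), as.numeric(vol))   # exact for double storage
  # pixdim is stored in single precision in the NIfTI-1 header
  expect_equal(attr(back, "voxel_size"), c(0.64, 0.64, 0.64),
               tolerance = 1e-6)

  vol4 <- array(rnorm(6 * 6 * 6 * 4), c(6, 6, 6, 4))
  f4 <- tempfile(fileext = ".nii.gz")
  write_volume(vol4, f4, voxel_size = 0.64)
  expect_equal(dim(read_volume(f4)), dim(vol4))

  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
  expect_error(write_volume(array(NA_real_, c(2, 2, 2)), f), "non-finite")
})
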