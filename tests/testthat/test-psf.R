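st <- simulation_tissues()

test_that("block phantom geometry: voxel counts and bounds", {
  ph <- make_block_phantom(150, 21, st$gm, st$wm)
  expect_equal(sum(ph$labels == 1L), 441L)
  expect_equal(sum(ph$labels == 0L), 22059L)
  # near-full square leaves a background ring
  ph2 <- make_block_phantom(150, 148, st$gm, st$wm)
  expect_true(all(ph2$labels[1, ] == 0L))
  expect_error(make_block_phantom(150, 150, st$gm, st$wm), "fg_extent")
  expect_error(make_block_phantom(150, 0, st$gm, st$wm), "fg_extent")
})

test_that("uniform phantom reconstructs to the closed-form UNI exactly", {
  p <- example_protocol("mp2rageme")
  res <- simulate_segmented_acquisition(make_block_phantom(150, 21, st$wm, st$wm), p)
  expect_equal(res$blur_pct, 0)
  expect_lt(max(abs(res$recon_image - res$uni_bg)), 1e-12)
  tab <- blur_profiles(res)
  expect_equal(tab$readout_profile, tab$slice_profile, tolerance = 1e-12)
  expect_equal(tab$readout_profile, tab$ideal, tolerance = 1e-12)
})

test_that("frozen magnetization removes all blurring", {
  # with identical signal at every excitation the reconstruction is exact,
  # attributing the blurring entirely to signal evolution across the readout
  p <- example_protocol("mp2rageme")
  ph <- make_block_phantom(150, 21, st$gm, st$wm)
  res <- simulate_segmented_acquisition(ph, p, frozen = TRUE)
  expect_lt(res$blur_pct, 1e-6)
  expect_lt(max(abs(res$profile_sl - res$ideal_sl)), 1e-12)
})

test_that("gray-matter square in white matter blurs by less than 10%", {
  p <- example_protocol("mp2rageme")
  res <- simulate_segmented_acquisition(make_block_phantom(150, 21, st$gm, st$wm), p)
  expect_gt(res$blur_pct, 0)
  expect_lt(res$blur_pct, 10)
})

test_that("the larger GM/CSF T1 difference blurs more than GM/WM", {
  for (nm in c("mp2rageme", "mp2rage")) {
    p <- example_protocol(nm)
    in_wm <- simulate_segmented_acquisition(make_block_phantom(150, 21, st$gm, st$wm), p)
    in_csf <- simulate_segmented_acquisition(make_block_phantom(150, 21, st$gm, st$csf), p)
    expect_gt(in_csf$blur_pct, in_wm$blur_pct)
  }
})

test_that("readout direction stays two-level; blurring lives along phase encode", {
  p <- example_protocol("mp2rageme")
  ph <- make_block_phantom(150, 21, st$gm, st$wm)
  res <- simulate_segmented_acquisition(ph, p)
  contrast <- abs(res$uni_fg - res$uni_bg)
  off <- ph$offset; ext <- ph$fg_extent
  bg_cols <- c(seq_len(off - 1L), (off + ext + 2L):150)
  # background columns pass only the DC line: exact to rounding
  expect_lt(max(abs(res$profile_ro[bg_cols] - res$ideal_ro[bg_cols])), 1e-12)
  # the foreground plateau is flat (a common small offset, no edge response)
  fg_cols <- (off + 2L):(off + ext - 1L)
  expect_lt(diff(range(res$profile_ro[fg_cols])), 1e-9)
  # and an order of magnitude smaller than the phase-encode edge deviation
  sl_edge <- max(abs(res$profile_sl - res$ideal_sl))
  ro_dev <- max(abs(res$profile_ro - res$ideal_ro))
  expect_lt(ro_dev, 0.1 * sl_edge)

  # phase-encode deviations above 1% of the contrast sit within 2 voxels of
  # the two boundaries
  dev <- abs(res$profile_sl - res$ideal_sl) / contrast
  near <- c((off - 1L):(off + 3L), (off + ext - 2L):(off + ext + 2L))
  expect_lt(max(dev[-near]), 0.01)
  expect_gt(max(dev[near]), 0.01)
})

test_that("compartment interiors keep the closed-form mean intensity", {
  for (bg in list(st$wm, st$csf)) {
    p <- example_protocol("mp2rageme")
    ph <- make_block_phantom(150, 21, st$gm, bg)
    res <- simulate_segmented_acquisition(ph, p)
    contrast <- abs(res$uni_fg - res$uni_bg)
    inner <- (ph$offset + 4L):(ph$offset + ph$fg_extent - 3L)
    fg_mean <- mean(res$recon_image[inner, inner])
    expect_lt(abs(fg_mean - res$uni_fg) / contrast, 0.005)
    bg_block <- res$recon_image[20:40, 20:40]
    expect_lt(abs(mean(bg_block) - res$uni_bg) / contrast, 0.005)
  }
})

test_that("blurring grows with the T1 difference across the boundary", {
  p <- example_protocol("mp2rageme")
  blur <- vapply(c(1.45, 1.15, 0.85), function(t1_bg) {
    bg <- tissue_params(t1_bg, 26.7, 0.70, "bg")
    simulate_segmented_acquisition(make_block_phantom(150, 21, st$gm, bg), p)$blur_pct
  }, numeric(1))
  expect_true(all(diff(blur) > 0))
})

test_that("grid/protocol size mismatch is an explicit error", {
  p <- example_protocol("mp2rageme")
  expect_error(
    simulate_segmented_acquisition(make_block_phantom(100, 21, st$gm, st$wm), p),
    "must match")
})
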