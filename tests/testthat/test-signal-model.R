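test_that("FLASH steady state matches a fixed-point Bloch iteration", {
  cases <- expand.grid(alpha = c(3, 6, 12, 30), tr = c(6.2, 31.4),
                       t1 = c(0.5, 1.15, 1.85, 4.0))
  for (i in seq_len(nrow(cases))) {
    expect_equal(
      flash_steady_state(cases$alpha[i], cases$tr[i], cases$t1[i]),
      flash_iterate(cases$alpha[i], cases$tr[i], cases$t1[i]),
      tolerance = 1e-8)
  }
  expect_equal(flash_steady_state(12, 31.4, 1.15), 0.1161875, tolerance = 1e-6)
})

test_that("FLASH limits: no excitation and full recovery", {
  expect_equal(flash_steady_state(0, 31.4, 1.15), 0)
  # tr >> t1: signal approaches m0 sin(alpha)
  expect_equal(flash_steady_state(20, 1e6, 0.5, m0 = 2), 2 * sin(20 * pi / 180),
               tolerance = 1e-8)
  expect_error(flash_steady_state(91, 31.4, 1.15), "alpha")
  expect_error(flash_steady_state(12, -1, 1.15), "tr")
})

test_that("FLASH signal is maximized at the Ernst angle", {
  for (tr in c(6.2, 31.4)) for (t1 in c(0.8, 1.15, 2.0)) {
    ernst <- acos(exp(-tr / (1000 * t1))) * 180 / pi
    grid <- seq(0.2, 45, by = 0.05)
    s <- flash_steady_state(grid, tr, t1)
    expect_equal(grid[which.max(s)], ernst, tolerance = 0.06)
    expect_true(all(s <= flash_steady_state(ernst, tr, t1) + 1e-12))
  }
})

test_that("UNI combination: extremal cases, scale invariance, oddness, bounds", {
  expect_equal(uni_combination(0, 3), 0)
  expect_equal(uni_combination(2, 2), 0.5)
  expect_equal(uni_combination(-2, 2), -0.5)
  set.seed(11)
  a <- rnorm(200); b <- rnorm(200)
  expect_equal(uni_combination(2 * a, 2 * b), uni_combination(a, b))
  expect_equal(uni_combination(-a, b), -uni_combination(a, b))
  u <- uni_combination(a, b)
  expect_true(all(u >= -0.5 & u <= 0.5))
  expect_warning(u0 <- uni_combination(0, 0), "undefined")
  expect_equal(as.numeric(u0), 0)
})

test_that("closed-form steady state agrees with a time-marching Bloch integrator", {
  # independent oracle: sub-ms time stepping through the whole sequence
  for (nm in c("mp2rageme", "mp2rage")) {
    p <- example_protocol(nm)
    for (t1 in c(0.5, 1.15, 1.85, 4.0)) {
      tis <- tissue_params(t1, 26.7, 1)
      cs <- simulate_cycle(p, tis)
      centre <- p$n_lines / 2 + 1
      m <- bloch_march(p, t1, cycles = 30)
      expect_equal(cs$mz_trace$block1[centre], m$m1, tolerance = 1e-6)
      expect_equal(cs$mz_trace$block2[centre], m$m2, tolerance = 1e-6)
      expect_equal(cs$uni, bloch_march_uni(p, t1, cycles = 30),
                   tolerance = 1e-6)
    }
  }
})

test_that("scaled flip angles (transmit-field factor) agree with the oracle", {
  p <- example_protocol("mp2rageme")
  for (b1 in c(0.8, 1.2)) {
    expect_equal(as.numeric(simulate_uni(p, 1.15, b1)),
                 bloch_march_uni(p, 1.15, b1, cycles = 30),
                 tolerance = 1e-6)
  }
})

test_that("affine fixed point equals the iterated periodic steady state", {
  p <- example_protocol("mp2rageme")
  tis <- tissue_params(1.85, 32.4, 0.82)
  a <- simulate_cycle(p, tis, method = "closed-form")
  b <- simulate_cycle(p, tis, method = "iterate", tol = 1e-14)
  expect_equal(a$mz_cycle_start, b$mz_cycle_start, tolerance = 1e-10)
  expect_equal(a$s1, b$s1, tolerance = 1e-10)
  expect_equal(a$s2, b$s2, tolerance = 1e-10)
})

test_that("degenerate regimes: no recovery, no inversion, echo decay", {
  p <- example_protocol("mp2rageme")
  # T1 much longer than the cycle: everything saturates to zero signal
  sat <- simulate_cycle(p, tissue_params(500, 26.7, 1))
  expect_lt(abs(sat$s1), 1e-3)
  expect_true(all(abs(sat$s2) < 1e-3))
  # disabled inversion: magnetization stays positive throughout block 1
  noinv <- simulate_cycle(p, tissue_params(1.15, 26.7, 1), inv_efficiency = 0)
  expect_true(all(noinv$mz_trace$block1 > 0))
  # echo amplitudes decay with TE
  cs <- simulate_cycle(p, tissue_params(1.15, 26.7, 1))
  expect_true(all(diff(abs(cs$s2)) < 0))
  expect_true(abs(cs$uni) <= 0.5)
})

test_that("matched first echoes cancel T2* in the UNI value", {
  p <- example_protocol("mp2rageme")   # te2[1] == te1 == 3 ms
  u <- vapply(c(10, 20, 35, 60), function(t2s)
    simulate_cycle(p, tissue_params(1.15, t2s, 1))$uni, numeric(1))
  expect_lt(diff(range(u)), 1e-12)
})

test_that("snr_ratio behaves at its limits", {
  expect_equal(snr_ratio(12, 12, 31.4, 1.15), 1)
  expect_equal(snr_ratio(6, 12, 1e7, 1.15),
               sin(6 * pi / 180) / sin(12 * pi / 180), tolerance = 1e-6)
})
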