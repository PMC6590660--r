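# Independent brute-force oracles used to validate the closed-form model.

# Time-marching Bloch integrator: walks through the whole sequence in
# sub-millisecond steps, applying instantaneous flips at the exact event
# times and exact mono-exponential T1 recovery within each step. Returns Mz
# immediately before the centre excitation of each block after `cycles`
# cycles starting from thermal equilibrium. Shares no code with the affine
# fixed-point solver in the package.
bloch_march <- function(p, t1, b1 = 1, eff = p$inv_efficiency, cycles = 40L) {
  t1ms <- 1000 * t1
  n <- p$n_lines
  g <- block_relaxation_times(p)
  flip_t <- c(0,
              g[["TA"]] + (0:(n - 1)) * p$tr_block1,
              g[["TA"]] + n * p$tr_block1 + g[["TB"]] + (0:(n - 1)) * p$tr_block2)
  flip_cos <- c(NA, rep(cos(b1 * p$alpha1 * pi / 180), n),
                rep(cos(b1 * p$alpha2 * pi / 180), n))
  t_cycle <- p$tr_cycle * 1000
  e1ms <- exp(-1 / t1ms)
  relax <- function(mz, dt) {
    while (dt > 1e-9) {
      h <- min(1, dt)
      mz <- 1 + (mz - 1) * (if (h == 1) e1ms else exp(-h / t1ms))
      dt <- dt - h
    }
    mz
  }
  centre1 <- 1L + n / 2 + 1L          # event index of block-1 centre flip
  centre2 <- 1L + n + n / 2 + 1L
  mz <- 1
  m1 <- m2 <- NA_real_
  for (cy in seq_len(cycles)) {
    tcur <- 0
    for (j in seq_along(flip_t)) {
      mz <- relax(mz, flip_t[j] - tcur)
      tcur <- flip_t[j]
      if (j == 1L) {
        mz <- -eff * mz
      } else {
        if (cy == cycles && j == centre1) m1 <- mz
        if (cy == cycles && j == centre2) m2 <- mz
        mz <- mz * flip_cos[j]
      }
    }
    mz <- relax(mz, t_cycle - tcur)
  }
  list(m1 = m1, m2 = m2)
}

# UNI from the marching oracle
bloch_march_uni <- function(p, t1, b1 = 1, eff = p$inv_efficiency, ...) {
  m <- bloch_march(p, t1, b1, eff, ...)
  s1 <- sin(b1 * p$alpha1 * pi / 180) * m$m1
  s2 <- sin(b1 * p$alpha2 * pi / 180) * m$m2
  s1 * s2 / (s1^2 + s2^2)
}

# fixed-point iteration oracle for the FLASH steady state: repeatedly apply
# excitation + recovery until the pre-excitation magnetization is stationary
flash_iterate <- function(alpha, tr, t1, m0 = 1, tol = 1e-14) {
  a <- alpha * pi / 180
  e1 <- exp(-tr / (1000 * t1))
  mz <- m0
  repeat {
    mz_new <- mz * cos(a) * e1 + m0 * (1 - e1)
    if (abs(mz_new - mz) < tol) break
    mz <- mz_new
  }
  mz * sin(a)
}

sim_tissues <- simulation_tissues()
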