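## Periodic steady-state Bloch model for MP2RAGE-family sequences.
##
## Longitudinal magnetization (normalized to M0 = 1) is propagated through
## one cycle by composing affine maps Mz -> A*Mz + B:
##   inversion          (A, B) = (-eff, 0)
##   free relaxation t  (A, B) = (E, 1 - E),          E = exp(-t/T1)
##   one readout line   (A, B) = (cos(a)*E, 1 - E),   E = exp(-TR/T1)
## n identical lines compose in closed form to (A^n, B*(1-A^n)/(1-A)), so the
## cycle map and the periodic steady state (fixed point B/(1-A)) are exact;
## no time stepping is involved. Transverse magnetization is assumed
## perfectly spoiled between excitations, and the transmit field scales the
## excitation flip angles only (the inversion is adiabatic).

deg2rad <- function(x) x * pi / 180

# sum_{k=0}^{m-1} a^k, stable near a = 1
.geom_sum <- function(a, m) ifelse(abs(1 - a) < 1e-12, m, (1 - a^m) / (1 - a))

# elementary affine pieces of one cycle; vector-safe over t1 or b1
.cycle_pieces <- function(p, t1, b1, eff) {
  g <- block_relaxation_times(p)
  t1ms <- 1000 * t1
  list(
    ea = exp(-g[["TA"]] / t1ms), eb = exp(-g[["TB"]] / t1ms),
    ec = exp(-g[["TC"]] / t1ms),
    e1 = exp(-p$tr_block1 / t1ms), e2 = exp(-p$tr_block2 / t1ms),
    c1 = cos(deg2rad(b1 * p$alpha1)), c2 = cos(deg2rad(b1 * p$alpha2)),
    s1 = sin(deg2rad(b1 * p$alpha1)), s2 = sin(deg2rad(b1 * p$alpha2)),
    eff = eff, n = p$n_lines
  )
}

# compose map 'f' followed by 'g'; maps are list(A, B)
.aff <- function(A, B) list(A = A, B = B)
.compose <- function(f, g) .aff(g$A * f$A, g$A * f$B + g$B)
.lines_map <- function(a_line, b_line, m) .aff(a_line^m, b_line * .geom_sum(a_line, m))

# full-cycle affine map, starting just before the inversion pulse
.cycle_map <- function(pc) {
  a1 <- pc$c1 * pc$e1; b1l <- 1 - pc$e1
  a2 <- pc$c2 * pc$e2; b2l <- 1 - pc$e2
  m <- .aff(-pc$eff, 0)
  m <- .compose(m, .aff(pc$ea, 1 - pc$ea))
  m <- .compose(m, .lines_map(a1, b1l, pc$n))
  m <- .compose(m, .aff(pc$eb, 1 - pc$eb))
  m <- .compose(m, .lines_map(a2, b2l, pc$n))
  .compose(m, .aff(pc$ec, 1 - pc$ec))
}

# steady-state Mz (M0 = 1) just before the centre excitation of each block;
# vectorized elementwise over t1 and/or b1 (lengths recycle)
.mz_centers <- function(p, t1, b1 = 1, eff = p$inv_efficiency) {
  pc <- .cycle_pieces(p, t1, b1, eff)
  a1 <- pc$c1 * pc$e1; b1l <- 1 - pc$e1
  a2 <- pc$c2 * pc$e2; b2l <- 1 - pc$e2
  n <- pc$n; k <- n / 2
  cyc <- .cycle_map(pc)
  mz0 <- cyc$B / (1 - cyc$A)        # before inversion
  to1 <- .compose(.compose(.aff(-pc$eff, 0), .aff(pc$ea, 1 - pc$ea)),
                  .lines_map(a1, b1l, k))
  m1 <- to1$A * mz0 + to1$B
  to2 <- .compose(.compose(.compose(to1, .lines_map(a1, b1l, n - k)),
                           .aff(pc$eb, 1 - pc$eb)),
                  .lines_map(a2, b2l, k))
  m2 <- to2$A * mz0 + to2$B
  list(m1 = m1, m2 = m2, mz0 = mz0)
}

# steady-state Mz before every excitation of both blocks (scalar t1, b1);
# mz0 (start-of-cycle magnetization) may be supplied to propagate from a
# state obtained by other means
.mz_trace <- function(p, t1, b1 = 1, eff = p$inv_efficiency, mz0 = NULL) {
  stopifnot(length(t1) == 1L, length(b1) == 1L)
  pc <- .cycle_pieces(p, t1, b1, eff)
  a1 <- pc$c1 * pc$e1; b1l <- 1 - pc$e1
  a2 <- pc$c2 * pc$e2; b2l <- 1 - pc$e2
  n <- pc$n
  cyc <- .cycle_map(pc)
  if (is.null(mz0)) mz0 <- cyc$B / (1 - cyc$A)
  m <- -pc$eff * mz0
  m <- m * pc$ea + (1 - pc$ea)
  mz1 <- numeric(n)
  for (i in seq_len(n)) { mz1[i] <- m; m <- m * a1 + b1l }
  m <- m * pc$eb + (1 - pc$eb)
  mz2 <- numeric(n)
  for (i in seq_len(n)) { mz2[i] <- m; m <- m * a2 + b2l }
  list(mz1 = mz1, mz2 = mz2, mz0 = mz0)
}

#' Steady-state spoiled gradient-echo (FLASH) signal
#'
#' Signal of an RF-spoiled gradient-echo train at steady state,
#' \code{m0 * sin(a) * (1 - E1) / (1 - cos(a) * E1)} with
#' \code{E1 = exp(-tr / (1000 * t1))}. Maximized at the Ernst angle
#' \code{acos(E1)}.
#'
#' @param alpha Flip angle in degrees, in \code{[0, 90]}.
#' @param tr Repetition time in ms.
#' @param t1 Longitudinal relaxation time in seconds.
#' @param m0 Equilibrium magnetization (arbitrary units).
#' @return Signal amplitude in the units of \code{m0}. Vectorized over all
#'   arguments.
#' @examples
#' flash_steady_state(12, 31.4, 1.15)
#' @export
flash_steady_state <- function(alpha, tr, t1, m0 = 1) {
  if (any(alpha < 0 | alpha > 90)) stop("'alpha' must be in [0, 90] degrees")
  if (any(tr <= 0)) stop("'tr' must be positive (ms)")
  if (any(t1 <= 0)) stop("'t1' must be positive (s)")
  e1 <- exp(-tr / (1000 * t1))
  a <- deg2rad(alpha)
  m0 * sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

#' Relative SNR of two FLASH flip angles
#'
#' Ratio of steady-state FLASH signals at two flip angles for the same TR and
#' T1. Used to quantify the SNR penalty of acquiring the second readout block
#' below the Ernst angle.
#'
#' @param alpha_low,alpha_high Flip angles in degrees, both in (0, 90].
#' @param tr Repetition time in ms.
#' @param t1 Longitudinal relaxation time in seconds.
#' @return \code{flash_steady_state(alpha_low, ...) /
#'   flash_steady_state(alpha_high, ...)}.
#' @examples
#' snr_ratio(6, 12, 31.4, 1.15)   # about 0.75 in white matter
#' @export
snr_ratio <- function(alpha_low, alpha_high, tr, t1) {
  if (any(alpha_low <= 0) || any(alpha_high <= 0))
    stop("flip angles must be positive")
  flash_steady_state(alpha_low, tr, t1) / flash_steady_state(alpha_high, tr, t1)
}

#' Ratio combination of the two inversion images
#'
#' The bias-free T1-weighted (UNI) combination
#' \code{s1 * s2 / (s1^2 + s2^2)}, bounded in \code{[-0.5, 0.5]} and
#' invariant under joint scaling of both inputs, which removes proton
#' density, receive-field and (for matched echo times) T2* weighting. For a
#' multi-echo second block the first echo is the one combined, since its TE
#' matches the first-block TE.
#'
#' @param s1,s2 Signed signal amplitudes (vectorized).
#' @return UNI values in \code{[-0.5, 0.5]}. Where both inputs are zero the
#'   value is defined as 0 and a warning is raised; the attribute
#'   \code{"degenerate"} carries the count of such entries.
#' @examples
#' uni_combination(1, 1)    # 0.5
#' uni_combination(-2, 2)   # -0.5
#' @export
uni_combination <- function(s1, s2) {
  denom <- s1^2 + s2^2
  degen <- denom == 0
  u <- ifelse(degen, 0, s1 * s2 / ifelse(degen, 1, denom))
  u <- pmin(pmax(u, -0.5), 0.5)
  if (any(degen)) {
    warning(sum(degen), " UNI value(s) undefined (s1 = s2 = 0), set to 0")
    attr(u, "degenerate") <- sum(degen)
  }
  u
}

#' UNI intensity of a protocol at given T1 and transmit field
#'
#' Convenience wrapper around the steady-state cycle model: returns the UNI
#' intensity for one or more T1 values (or transmit-field factors) without
#' constructing full echo sets. Since the first echoes of the two blocks have
#' matched TE, T2* cancels and is not needed.
#'
#' @param p An \code{mp2rage_protocol}.
#' @param t1 T1 values in seconds (vectorized).
#' @param b1 Relative transmit-field factor(s); flip angles are scaled by
#'   \code{b1}.
#' @param inv_efficiency Inversion efficiency; defaults to the protocol's.
#' @return UNI values, recycled elementwise over \code{t1} and \code{b1}.
#' @examples
#' simulate_uni(example_protocol("mp2rageme"), c(1.15, 1.85, 4.0))
#' @export
simulate_uni <- function(p, t1, b1 = 1, inv_efficiency = p$inv_efficiency) {
  stopifnot(inherits(p, "mp2rage_protocol"))
  if (any(b1 <= 0)) stop("'b1' must be positive")
  m <- .mz_centers(p, t1, b1, inv_efficiency)
  uni_combination(sin(deg2rad(b1 * p$alpha1)) * m$m1,
                  sin(deg2rad(b1 * p$alpha2)) * m$m2)
}

#' Simulate one steady-state cycle of an MP2RAGE-family sequence
#'
#' Propagates longitudinal magnetization through the periodic steady state of
#' the sequence (inversion, relaxation gap TA, first readout block,
#' gap TB, second readout block, gap TC) and returns the signed echo signals
#' read at the centre excitation of each block, together with the UNI
#' combination and the per-excitation Mz trace.
#'
#' The steady state is obtained from the exact affine fixed point of the
#' cycle map (\code{method = "closed-form"}), or, mainly for verification, by
#' iterating the cycle map from thermal equilibrium until the start-of-cycle
#' magnetization is periodic to within \code{tol} (\code{method =
#' "iterate"}).
#'
#' @param p An \code{mp2rage_protocol}.
#' @param tissue A \code{tissue_params} object.
#' @param b1 Relative transmit-field factor (scales both excitation flip
#'   angles; the inversion is adiabatic and unaffected).
#' @param inv_efficiency Inversion efficiency; defaults to the protocol's.
#' @param method Steady-state solver, see Details.
#' @param tol,max_iter Convergence control for \code{method = "iterate"}.
#' @return An object of class \code{echo_signal_set}: signed signals
#'   \code{s1} (first block, TE1) and \code{s2} (second block, one per TE),
#'   the \code{uni} value computed from \code{s1} and the first second-block
#'   echo, and \code{mz_trace}, a list with Mz before every excitation of
#'   each block.
#' @examples
#' wm <- tissue_params(1.15, 26.7, 0.70, "WM")
#' simulate_cycle(example_protocol("mp2rageme"), wm)
#' @export
simulate_cycle <- function(p, tissue, b1 = 1,
                           inv_efficiency = p$inv_efficiency,
                           method = c("closed-form", "iterate"),
                           tol = 1e-10, max_iter = 500L) {
  stopifnot(inherits(p, "mp2rage_protocol"), inherits(tissue, "tissue_params"))
  if (length(b1) != 1L || b1 <= 0) stop("'b1' must be a single positive number")
  method <- match.arg(method)

  if (method == "iterate") {
    pc <- .cycle_pieces(p, tissue$t1, b1, inv_efficiency)
    cyc <- .cycle_map(pc)
    mz <- 1; converged <- FALSE
    for (it in seq_len(max_iter)) {
      mz_new <- cyc$A * mz + cyc$B
      if (abs(mz_new - mz) <= tol * max(1, abs(mz_new))) { converged <- TRUE; mz <- mz_new; break }
      mz <- mz_new
    }
    if (!converged)
      stop("cycle iteration did not reach a periodic steady state after ",
           max_iter, " cycles")
    tr <- .mz_trace(p, tissue$t1, b1, inv_efficiency, mz0 = mz)
  } else {
    tr <- .mz_trace(p, tissue$t1, b1, inv_efficiency)
  }

  n <- p$n_lines; centre <- n / 2 + 1L
  sin1 <- sin(deg2rad(b1 * p$alpha1))
  sin2 <- sin(deg2rad(b1 * p$alpha2))
  s1 <- tissue$m0 * sin1 * tr$mz1[centre] * exp(-p$te1 / tissue$t2star)
  s2 <- tissue$m0 * sin2 * tr$mz2[centre] * exp(-p$te2 / tissue$t2star)
  uni <- uni_combination(s1, if (length(s2) > 0L) s2[1L] else s1)
  structure(list(s1 = s1, s2 = s2, uni = as.numeric(uni),
                 mz_trace = list(block1 = tr$mz1, block2 = tr$mz2),
                 mz_cycle_start = tr$mz0,
                 tissue = tissue, b1 = b1, protocol = p$name,
                 method = method),
            class = "echo_signal_set")
}

#' @export
print.echo_signal_set <- function(x, ...) {
  cat(sprintf("echo signals, protocol '%s', tissue '%s' (T1 %.3f s), B1 %.2f\n",
              x$protocol, x$tissue$label, x$tissue$t1, x$b1))
  cat(sprintf("  s1 = %.5f; s2 = %s\n", x$s1,
              paste(sprintf("%.5f", x$s2), collapse = ", ")))
  cat(sprintf("  UNI = %.5f\n", x$uni))
  invisible(x)
}
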