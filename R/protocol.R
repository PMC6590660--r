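#' Define an MP2RAGE-family acquisition protocol
#'
#' An MP2RAGE-family protocol is a segmented inversion-recovery sequence: each
#' cycle of duration \code{tr_cycle} starts with an adiabatic inversion pulse,
#' followed by two spoiled gradient-echo (FLASH) readout blocks of
#' \code{n_lines} excitations each, placed so that the centre excitation of
#' block 1 falls at \code{ti1} and that of block 2 at \code{ti2} after the
#' inversion. The second block may acquire several echoes per excitation
#' (\code{te2}); a single-element \code{te2} describes a plain MP2RAGE.
#'
#' Inversion times follow the standard convention of linear (sequential)
#' phase-encode ordering: TI refers to the temporal centre of its readout
#' block, i.e. the moment the centre of k-space is acquired. All timing
#' arithmetic is done in milliseconds; only the cycle TR is given in seconds,
#' matching how such protocols are usually printed.
#'
#' @param tr_cycle Cycle repetition time TR_MP2RAGE between successive
#'   inversion pulses, in seconds.
#' @param tr_block1,tr_block2 Excitation repetition times of the first and
#'   second GRE block, in ms.
#' @param te1 Echo time of the first block, in ms.
#' @param te2 Numeric vector of echo times of the second block, in ms,
#'   strictly increasing. Length one gives a plain MP2RAGE.
#' @param ti1,ti2 Inversion times of the two blocks (inversion pulse to block
#'   centre), in ms.
#' @param alpha1,alpha2 Nominal excitation flip angles of the two blocks, in
#'   degrees.
#' @param n_lines Number of excitations (phase-encode lines) per block.
#' @param n_readouts Number of cycles (outer phase-encode loop).
#' @param inv_efficiency Inversion efficiency in (0, 1]; the inversion maps
#'   Mz to \code{-inv_efficiency * Mz}. Defaults to 0.96, a typical adiabatic
#'   value.
#' @param name Optional protocol name used in printing and reports.
#'
#' @return An object of class \code{mp2rage_protocol}.
#' @seealso [block_relaxation_times()], [timing_audit()], [simulate_cycle()],
#'   [read_protocol()]
#' @examples
#' p <- example_protocol("mp2rageme")
#' block_relaxation_times(p)
#' @export
protocol_params <- function(tr_cycle, tr_block1, tr_block2, te1, te2,
                            ti1, ti2, alpha1, alpha2, n_lines,
                            n_readouts = 1L, inv_efficiency = 0.96,
                            name = "protocol") {
  num1 <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", what, "' must be a single finite number", call. = FALSE)
    as.numeric(x)
  }
  te2 <- as.numeric(te2)
  if (length(te2) > 0L && any(diff(te2) <= 0))
    stop("'te2' must be strictly increasing", call. = FALSE)
  p <- structure(list(
    tr_cycle = num1(tr_cycle, "tr_cycle"),
    tr_block1 = num1(tr_block1, "tr_block1"),
    tr_block2 = num1(tr_block2, "tr_block2"),
    te1 = num1(te1, "te1"),
    te2 = te2,
    ti1 = num1(ti1, "ti1"),
    ti2 = num1(ti2, "ti2"),
    alpha1 = num1(alpha1, "alpha1"),
    alpha2 = num1(alpha2, "alpha2"),
    n_lines = as.integer(num1(n_lines, "n_lines")),
    n_readouts = as.integer(num1(n_readouts, "n_readouts")),
    inv_efficiency = num1(inv_efficiency, "inv_efficiency"),
    name = as.character(name)[1L]
  ), class = "mp2rage_protocol")
  validate_protocol(p)
  p
}

#' @rdname protocol_params
#' @param p An \code{mp2rage_protocol} object.
#' @export
validate_protocol <- function(p) {
  stopifnot(inherits(p, "mp2rage_protocol"))
  with(p, {
    if (tr_cycle <= 0 || tr_block1 <= 0 || tr_block2 <= 0)
      stop("repetition times must be positive", call. = FALSE)
    if (alpha1 < 0 || alpha1 > 90 || alpha2 < 0 || alpha2 > 90)
      stop("flip angles must lie in [0, 90] degrees", call. = FALSE)
    if (n_lines < 2L || n_lines %% 2L != 0L)
      stop("'n_lines' must be an even count of at least 2", call. = FALSE)
    if (inv_efficiency <= 0 || inv_efficiency > 1)
      stop("'inv_efficiency' must be in (0, 1]", call. = FALSE)
    if (te1 >= tr_block1)
      stop("te1 must be shorter than tr_block1", call. = FALSE)
    if (length(te2) > 0L && max(te2) >= tr_block2)
      stop("all te2 must be shorter than tr_block2", call. = FALSE)
  })
  block_relaxation_times(p)   # errors on any negative gap
  invisible(p)
}

#' Relaxation gaps of one sequence cycle
#'
#' Splits the cycle TR into the three free-relaxation gaps around the two
#' readout blocks: TA between the inversion pulse and the start of block 1,
#' TB between the blocks, and TC from the end of block 2 to the next
#' inversion. The inversion pulse itself is modelled as instantaneous, so
#' \code{TA + n_lines*tr_block1 + TB + n_lines*tr_block2 + TC} equals the
#' cycle TR exactly.
#'
#' @param p An \code{mp2rage_protocol}.
#' @return Named numeric vector \code{c(TA=, TB=, TC=)} in ms.
#' @examples
#' block_relaxation_times(example_protocol("mp2rage"))
#' @export
block_relaxation_times <- function(p) {
  stopifnot(inherits(p, "mp2rage_protocol"))
  half <- p$n_lines / 2
  ta <- p$ti1 - half * p$tr_block1
  tb <- (p$ti2 - p$ti1) - half * (p$tr_block1 + p$tr_block2)
  tc <- p$tr_cycle * 1000 - p$ti2 - half * p$tr_block2
  g <- c(TA = ta, TB = tb, TC = tc)
  bad <- names(g)[g < -1e-9]
  if (length(bad) > 0L)
    stop("invalid protocol '", p$name, "': relaxation gap ",
         paste(bad, collapse = ", "), " is negative (",
         paste(sprintf("%.2f", g[bad]), collapse = ", "), " ms)",
         call. = FALSE)
  pmax(g, 0)
}

#' Scan-duration and dead-time audit of a protocol
#'
#' The dead time of a segmented inversion-recovery sequence is the part of
#' the cycle with neither excitation nor readout. Two natural definitions
#' exist and both are reported: the total of all three relaxation gaps
#' (TA+TB+TC), and the tail gap TC alone (the recovery interval that a
#' further readout could occupy). Scan duration is the number of cycles times
#' the cycle TR.
#'
#' @param p An \code{mp2rage_protocol}.
#' @return A list with \code{scan_duration} (s), \code{dead_fraction_total}
#'   and \code{dead_fraction_tail} (both in percent of the cycle TR).
#' @examples
#' timing_audit(example_protocol("mp2rageme"))
#' @export
timing_audit <- function(p) {
  g <- block_relaxation_times(p)
  cyc_ms <- p$tr_cycle * 1000
  list(scan_duration = p$n_readouts * p$tr_cycle,
       dead_fraction_total = 100 * sum(g) / cyc_ms,
       dead_fraction_tail = 100 * g[["TC"]] / cyc_ms)
}

#' Read a protocol definition from a YAML file
#'
#' The YAML keys mirror the arguments of [protocol_params()]. Files whose
#' keys are \code{tr}, \code{alpha} and \code{te} instead describe a plain
#' multi-echo FLASH (spoiled GRE) acquisition and are returned as a
#' \code{gre_protocol} list for use with [flash_steady_state()].
#'
#' @param path Path to a YAML file.
#' @return An \code{mp2rage_protocol} or a \code{gre_protocol}.
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (!is.null(y$ti1)) {
    do.call(protocol_params, y)
  } else {
    for (k in c("tr", "alpha", "te"))
      if (is.null(y[[k]])) stop("GRE protocol file misses key '", k, "'", call. = FALSE)
    structure(list(tr = y$tr, alpha = y$alpha, te = as.numeric(y$te),
                   name = if (is.null(y$name)) "gre" else y$name),
              class = "gre_protocol")
  }
}

#' Bundled example protocols
#'
#' Returns one of the protocol definitions shipped with the package:
#' \code{"mp2rageme"} (cycle TR 6.72 s, TI 670/3855 ms, four echoes),
#' \code{"mp2rage"} (cycle TR 6 s, TI 1000/3200 ms, single echo) or
#' \code{"megre"} (multi-echo FLASH, TR 31.4 ms, 12 degrees). The two
#' inversion-recovery fixtures use an ideal inversion
#' (\code{inv_efficiency = 1}).
#'
#' @param name One of \code{"mp2rageme"}, \code{"mp2rage"}, \code{"megre"}.
#' @return An \code{mp2rage_protocol} or \code{gre_protocol}.
#' @export
example_protocol <- function(name = c("mp2rageme", "mp2rage", "megre")) {
  name <- match.arg(name)
  path <- system.file("extdata", "protocols", paste0(name, ".yaml"),
                      package = "mp2rageme", mustWork = TRUE)
  read_protocol(path)
}

#' @export
print.mp2rage_protocol <- function(x, ...) {
  g <- block_relaxation_times(x)
  cat(sprintf("MP2RAGE-family protocol '%s'\n", x$name))
  cat(sprintf("  cycle TR %.3f s, %d lines x %d readouts\n",
              x$tr_cycle, x$n_lines, x$n_readouts))
  cat(sprintf("  block 1: TI %.0f ms, TR %.1f ms, TE %.1f ms, flip %.1f deg\n",
              x$ti1, x$tr_block1, x$te1, x$alpha1))
  cat(sprintf("  block 2: TI %.0f ms, TR %.1f ms, TE %s ms, flip %.1f deg\n",
              x$ti2, x$tr_block2, paste(x$te2, collapse = "/"), x$alpha2))
  cat(sprintf("  gaps TA/TB/TC = %.0f/%.0f/%.0f ms, inversion efficiency %.2f\n",
              g[["TA"]], g[["TB"]], g[["TC"]], x$inv_efficiency))
  invisible(x)
}
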