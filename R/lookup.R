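## Lookup-table T1 estimation with transmit-field correction.
##
## The forward model maps (T1, B1) to a UNI intensity; T1 estimation inverts
## it on the branch where UNI is strictly monotone in T1. Decoding at a
## voxel's measured relative B1 removes the residual transmit-field bias of
## the UNI contrast.

# longest strictly-decreasing run of u; returns c(first, last) indices
.monotone_branch <- function(u) {
  d <- diff(u) < 0
  if (!any(d)) return(c(NA_integer_, NA_integer_))
  r <- rle(d)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  len <- ifelse(r$values, r$lengths, 0L)
  i <- which.max(len)
  c(starts[i], ends[i] + 1L)   # run of diffs -> run of points
}

#' Build a (UNI, B1) to T1 lookup table
#'
#' Tabulates the forward signal model over a T1 grid for each value of a
#' relative transmit-field grid, and identifies, per B1 column, the branch on
#' which the UNI intensity is strictly decreasing in T1. T1 decoding is only
#' defined on that branch; the short-T1 fold-over tail is excluded.
#'
#' @param p An \code{mp2rage_protocol}.
#' @param t1_grid Strictly increasing T1 grid in seconds. The default spans
#'   0.1 to 6 s at 1 ms, giving sub-millisecond quantization error.
#' @param b1_grid Strictly increasing relative transmit-field grid. The
#'   default 0.6 to 1.4 at 0.01 covers realistic 7 T transmit variation with
#'   margin.
#' @param inv_efficiency Inversion efficiency used in the forward model.
#'   Defaults to 1 (ideal adiabatic inversion), the convention also used for
#'   the protocol fixtures.
#' @return An object of class \code{mp2rage_lut}: \code{t1_grid},
#'   \code{b1_grid}, the \code{uni} matrix (T1 by B1) and the per-column
#'   monotone \code{branch} index matrix.
#' @examples
#' lut <- build_lookup(example_protocol("mp2rage"),
#'                     t1_grid = seq(0.5, 5, by = 0.01), b1_grid = 1)
#' @export
build_lookup <- function(p, t1_grid = seq(0.1, 6, by = 0.001),
                         b1_grid = seq(0.6, 1.4, by = 0.01),
                         inv_efficiency = 1) {
  stopifnot(inherits(p, "mp2rage_protocol"))
  t1_grid <- as.numeric(t1_grid); b1_grid <- as.numeric(b1_grid)
  if (any(diff(t1_grid) <= 0) || (length(b1_grid) > 1L && any(diff(b1_grid) <= 0)))
    stop("grids must be strictly increasing")
  uni <- vapply(b1_grid,
                function(b) as.numeric(simulate_uni(p, t1_grid, b, inv_efficiency)),
                numeric(length(t1_grid)))
  uni <- matrix(uni, nrow = length(t1_grid))
  branch <- vapply(seq_along(b1_grid), function(j) {
    br <- .monotone_branch(uni[, j])
    if (anyNA(br) || (br[2] - br[1] + 1L) < length(t1_grid) / 2)
      stop("UNI is not monotone in T1 over most of the grid at B1 = ",
           b1_grid[j], "; fold-over near T1 = ",
           signif(t1_grid[max(br[1], 1L, na.rm = TRUE)], 3),
           " s (pathological protocol)", call. = FALSE)
    br
  }, integer(2))
  structure(list(t1_grid = t1_grid, b1_grid = b1_grid, uni = uni,
                 branch = branch, protocol = p$name,
                 inv_efficiency = inv_efficiency),
            class = "mp2rage_lut")
}

#' Decode T1 from UNI intensities through a lookup table
#'
#' Inverts the tabulated signal model voxelwise: the UNI column at each
#' voxel's relative transmit field is formed by linear interpolation between
#' the two neighbouring B1 columns, and the strictly monotone branch of that
#' column is inverted by vectorized bisection with linear interpolation
#' inside the bracketing 1-ms grid cell (the grid is fine enough that the
#' in-cell interpolation error is far below the grid quantization). UNI
#' values outside the monotone branch are clamped to the branch ends and
#' flagged invalid; ambiguous short-T1 fold-over solutions are thereby
#' resolved to the long-T1 branch.
#'
#' @param lut An \code{mp2rage_lut} from [build_lookup()].
#' @param uni UNI values in \code{[-0.5, 0.5]} (any shape; vectorized).
#' @param b1 Relative transmit field, recycled to the length of \code{uni}.
#'   Values outside the table's B1 grid are clamped (a warning reports the
#'   count).
#' @return A list with \code{t1} (seconds, same shape as \code{uni}) and
#'   logical \code{valid}.
#' @export
lookup_t1 <- function(lut, uni, b1 = 1) {
  stopifnot(inherits(lut, "mp2rage_lut"))
  dims <- dim(uni)
  u <- as.numeric(uni)
  b1 <- rep_len(as.numeric(b1), length(u))
  rng <- range(lut$b1_grid)
  n_clamp <- sum(b1 < rng[1] | b1 > rng[2], na.rm = TRUE)
  if (n_clamp > 0L)
    warning(n_clamp, " B1 value(s) outside the lookup grid [",
            rng[1], ", ", rng[2], "] were clamped")
  b1 <- pmin(pmax(ifelse(is.finite(b1), b1, 1), rng[1]), rng[2])

  nt <- length(lut$t1_grid)
  nb <- length(lut$b1_grid)
  if (nb == 1L) {
    j <- rep(1L, length(u)); jn <- j; w <- 0
  } else {
    j <- findInterval(b1, lut$b1_grid, all.inside = TRUE)
    jn <- j + 1L
    w <- (b1 - lut$b1_grid[j]) / (lut$b1_grid[jn] - lut$b1_grid[j])
    w <- pmin(pmax(w, 0), 1)
  }
  offA <- (j - 1L) * nt
  offB <- (jn - 1L) * nt
  ucol <- function(i) (1 - w) * lut$uni[i + offA] + w * lut$uni[i + offB]

  i0 <- pmax(lut$branch[1L, j], lut$branch[1L, jn])   # branch intersection
  i1 <- pmin(lut$branch[2L, j], lut$branch[2L, jn])
  hi <- ucol(i0); lo <- ucol(i1)                      # uni decreasing in T1
  finite <- is.finite(u)
  valid <- finite & u <= hi & u >= lo
  uc <- pmin(pmax(ifelse(finite, u, lo), lo), hi)

  lo_i <- i0; hi_i <- i1
  while (any(hi_i - lo_i > 1L)) {
    mid <- (lo_i + hi_i) %/% 2L
    above <- ucol(mid) >= uc        # target lies at mid or longer T1
    lo_i <- ifelse(above, mid, lo_i)
    hi_i <- ifelse(above, hi_i, mid)
  }
  u_lo <- ucol(lo_i); u_hi <- ucol(hi_i)
  f <- ifelse(u_hi == u_lo, 0, (uc - u_lo) / (u_hi - u_lo))
  t1 <- lut$t1_grid[lo_i] + f * (lut$t1_grid[hi_i] - lut$t1_grid[lo_i])

  dim(t1) <- dims; dim(valid) <- dims
  list(t1 = t1, valid = valid, b1_clamped = n_clamp)
}

#' T1 map from a UNI volume and a relative transmit-field volume
#'
#' Voxelwise lookup-table inversion of a UNI volume. If the transmit-field
#' volume is at a lower resolution than the UNI volume it is median-smoothed
#' and trilinearly resampled onto the UNI grid first; if it is missing,
#' nominal transmit (B1 = 1) is assumed and a prominent warning is issued.
#'
#' @param uni_vol Array of UNI intensities.
#' @param b1_vol Array of relative transmit-field factors, same
#'   dimensionality as \code{uni_vol} (any size), or \code{NULL}.
#' @param lut An \code{mp2rage_lut} built for the acquiring protocol.
#' @return A list with \code{t1_map} (seconds) and \code{validity_mask};
#'   voxels whose UNI fell outside the monotone branch are clamped to the
#'   branch ends and masked invalid.
#' @export
t1_from_uni <- function(uni_vol, b1_vol = NULL, lut) {
  stopifnot(inherits(lut, "mp2rage_lut"))
  if (is.null(b1_vol)) {
    warning("no B1 map supplied: decoding at nominal transmit (B1 = 1); ",
            "T1 values are uncorrected for transmit-field inhomogeneity")
    b1_vol <- 1
  } else if (!is.null(dim(uni_vol)) && !is.null(dim(b1_vol)) &&
             !identical(dim(uni_vol), dim(b1_vol))) {
    b1_vol <- resample_b1(b1_vol, dim(uni_vol))
  }
  res <- lookup_t1(lut, uni_vol, b1_vol)
  list(t1_map = res$t1, validity_mask = res$valid)
}

#' Resample a low-resolution transmit-field map onto a target grid
#'
#' Median-smooths the map (3-voxel cube) to suppress outliers, then resamples
#' it by trilinear interpolation onto the target grid, assuming both grids
#' cover the same field of view.
#'
#' @param b1 3-D array of relative transmit-field values.
#' @param dim_out Integer vector of target dimensions.
#' @param smooth Apply the median filter before resampling.
#' @return A 3-D array of dimension \code{dim_out}.
#' @export
resample_b1 <- function(b1, dim_out, smooth = TRUE) {
  stopifnot(length(dim(b1)) == 3L, length(dim_out) == 3L)
  if (smooth && all(dim(b1) >= 3L)) b1 <- .median_filter3(b1)
  .trilinear_resample(b1, dim_out)
}

# 3x3x3 median filter with edge replication
.median_filter3 <- function(a) {
  d <- dim(a)
  idx <- function(n) cbind(pmax(seq_len(n) - 1L, 1L), seq_len(n),
                           pmin(seq_len(n) + 1L, n))
  ix <- idx(d[1]); iy <- idx(d[2]); iz <- idx(d[3])
  stack <- matrix(0, length(a), 27L)
  k <- 0L
  for (ox in 1:3) for (oy in 1:3) for (oz in 1:3) {
    k <- k + 1L
    stack[, k] <- a[ix[, ox], iy[, oy], iz[, oz]]
  }
  out <- apply(stack, 1L, stats::median)
  dim(out) <- d
  out
}

# trilinear resampling between aligned grids sharing a field of view
.trilinear_resample <- function(a, dim_out) {
  d <- dim(a)
  coord <- function(n_out, n_in) {
    x <- ((seq_len(n_out) - 0.5) / n_out) * n_in + 0.5   # 1-based src coords
    pmin(pmax(x, 1), n_in)
  }
  cx <- coord(dim_out[1], d[1]); cy <- coord(dim_out[2], d[2])
  cz <- coord(dim_out[3], d[3])
  fx <- pmin(floor(cx), d[1] - 1L); fy <- pmin(floor(cy), max(d[2] - 1L, 1L))
  fz <- pmin(floor(cz), max(d[3] - 1L, 1L))
  if (d[1] == 1L) fx <- rep(1, dim_out[1])
  wx <- cx - fx; wy <- cy - fy; wz <- cz - fz
  gx <- pmin(fx + 1L, d[1]); gy <- pmin(fy + 1L, d[2]); gz <- pmin(fz + 1L, d[3])
  out <- array(0, dim_out)
  WX <- array(wx, dim_out)
  WY <- array(rep(wy, each = dim_out[1]), dim_out)
  WZ <- array(rep(wz, each = dim_out[1] * dim_out[2]), dim_out)
  for (cxn in 0:1) for (cyn in 0:1) for (czn in 0:1) {
    ix <- if (cxn == 0) fx else gx
    iy <- if (cyn == 0) fy else gy
    iz <- if (czn == 0) fz else gz
    w <- (if (cxn == 0) 1 - WX else WX) *
         (if (cyn == 0) 1 - WY else WY) *
         (if (czn == 0) 1 - WZ else WZ)
    out <- out + w * a[ix, iy, iz]
  }
  out
}

#' @export
print.mp2rage_lut <- function(x, ...) {
  cat(sprintf("UNI-to-T1 lookup table, protocol '%s'\n", x$protocol))
  cat(sprintf("  T1 grid: %.3f..%.3f s (%d points); B1 grid: %.2f..%.2f (%d)\n",
              min(x$t1_grid), max(x$t1_grid), length(x$t1_grid),
              min(x$b1_grid), max(x$b1_grid), length(x$b1_grid)))
  invisible(x)
}
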