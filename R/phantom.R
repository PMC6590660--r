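## Synthetic 3-D multi-tissue phantom.
##
## The generator emulates what the acquisition produces: per-echo magnitude
## and phase volumes of a brain-like nested-ellipsoid object with per-tissue
## T1/T2*/M0, a smooth relative transmit field, and Rician magnitude noise
## from complex Gaussian noise. Ground-truth maps are returned alongside so
## that the quantification pipeline can be validated by parameter recovery.

#' Configuration of the synthetic phantom
#'
#' @param grid_shape Integer vector of three voxel counts.
#' @param voxel_size Isotropic voxel size in mm.
#' @param tissue_table Data frame as returned by [default_tissues()]
#'   (columns \code{label}, \code{name}, \code{t1}, \code{t2star},
#'   \code{m0}).
#' @param b1_range Range of the smooth relative transmit field; the field is
#'   a radial quadratic peaking at the volume centre, emulating the
#'   centre-bright transmit profile of a head coil at 7 T.
#' @param snr Signal-to-noise ratio defining the noise SD as the white-matter
#'   first-echo signal of the second block divided by \code{snr}.
#'   \code{Inf} disables noise; nonpositive values disable it with a warning.
#' @param seed Integer seed; fully determines the generated volumes.
#' @param b1_decimate Optional integer factor; if given, the returned
#'   transmit-field map is additionally block-averaged down by this factor,
#'   emulating a separately acquired low-resolution map that the pipeline
#'   must resample.
#' @return An object of class \code{phantom_config}.
#' @export
phantom_config <- function(grid_shape = c(48L, 48L, 48L), voxel_size = 0.64,
                           tissue_table = default_tissues(),
                           b1_range = c(0.8, 1.2), snr = 30, seed = 1L,
                           b1_decimate = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
            length(b1_range) == 2L, b1_range[1] < b1_range[2],
            all(c("label", "name", "t1", "t2star", "m0") %in% names(tissue_table)))
  if (any(tissue_table$t1 <= 0) || any(tissue_table$t2star <= 0) ||
      any(tissue_table$m0 < 0))
    stop("tissue parameters must be positive (m0 nonnegative)")
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 tissue_table = tissue_table, b1_range = as.numeric(b1_range),
                 snr = snr, seed = as.integer(seed),
                 b1_decimate = b1_decimate),
            class = "phantom_config")
}

# nested-ellipsoid label layout on normalized [-1, 1] coordinates
.phantom_labels <- function(shape, tissue_table) {
  cx <- (seq_len(shape[1]) - 0.5) / shape[1] * 2 - 1
  cy <- (seq_len(shape[2]) - 0.5) / shape[2] * 2 - 1
  cz <- (seq_len(shape[3]) - 0.5) / shape[3] * 2 - 1
  X <- array(cx, shape)
  Y <- array(rep(cy, each = shape[1]), shape)
  Z <- array(rep(cz, each = shape[1] * shape[2]), shape)
  r2 <- (X / 0.95)^2 + (Y / 0.90)^2 + (Z / 0.95)^2
  lab_of <- function(name) tissue_table$label[match(name, tissue_table$name)]
  labels <- array(0L, shape)
  labels[r2 <= 1.00] <- lab_of("CSF")
  labels[r2 <= 0.80] <- lab_of("GM")
  labels[r2 <= 0.55] <- lab_of("WM")
  sphere <- function(x0, y0, z0, rad) (X - x0)^2 + (Y - y0)^2 + (Z - z0)^2 <= rad^2
  # lateral ventricles (CSF) and deep gray-matter nuclei inside the WM core
  labels[sphere(-0.16, 0.05, 0.12, 0.10) | sphere(0.16, 0.05, 0.12, 0.10)] <- lab_of("CSF")
  nuclei <- list(
    caudate = list(c(-0.28, 0.18, 0.10), 0.09), caudate_r = list(c(0.28, 0.18, 0.10), 0.09),
    putamen = list(c(-0.34, 0.00, 0.00), 0.10), putamen_r = list(c(0.34, 0.00, 0.00), 0.10),
    thalamus = list(c(-0.14, -0.14, 0.00), 0.11), thalamus_r = list(c(0.14, -0.14, 0.00), 0.11),
    red_nucleus = list(c(-0.07, -0.28, -0.12), 0.05), red_nucleus_r = list(c(0.07, -0.28, -0.12), 0.05),
    substantia_nigra = list(c(-0.15, -0.30, -0.16), 0.05), substantia_nigra_r = list(c(0.15, -0.30, -0.16), 0.05),
    STN = list(c(-0.11, -0.22, -0.20), 0.045), STN_r = list(c(0.11, -0.22, -0.20), 0.045))
  for (nm in names(nuclei)) {
    base <- sub("_r$", "", nm)
    if (!base %in% tissue_table$name) next
    ctr <- nuclei[[nm]][[1]]
    labels[sphere(ctr[1], ctr[2], ctr[3], nuclei[[nm]][[2]])] <- lab_of(base)
  }
  list(labels = labels, X = X, Y = Y, Z = Z)
}

# block-average decimation by an integer factor
.decimate <- function(a, f) {
  d <- dim(a)
  dn <- pmax(d %/% f, 1L)
  out <- array(0, dn)
  cnt <- array(0, dn)
  ix <- pmin((seq_len(d[1]) - 1L) %/% f + 1L, dn[1])
  iy <- pmin((seq_len(d[2]) - 1L) %/% f + 1L, dn[2])
  iz <- pmin((seq_len(d[3]) - 1L) %/% f + 1L, dn[3])
  grp <- array(0L, d)
  grp[] <- ix + (rep(iy, each = d[1]) - 1L) * dn[1] +
    (rep(iz, each = d[1] * d[2]) - 1L) * dn[1] * dn[2]
  sums <- tapply(as.numeric(a), as.integer(grp), sum)
  ns <- tapply(rep(1, length(a)), as.integer(grp), sum)
  out[as.integer(names(sums))] <- sums / ns
  out
}

#' Generate synthetic multi-echo volumes from the signal model
#'
#' Simulates the volumes an MP2RAGE-family acquisition of the phantom would
#' produce: the first-inversion echo and all second-inversion echoes, as
#' magnitude and phase volumes, plus the relative transmit-field map and the
#' ground-truth T1/T2*/M0/label volumes. Each voxel's signal comes from the
#' periodic steady-state cycle model at the voxel's local transmit field,
#' decayed to each echo time with the tissue T2*; phase is a smooth synthetic
#' field growing linearly with TE (no susceptibility physics). Noise is added
#' to the complex signal as i.i.d. Gaussian on both channels, making the
#' magnitude Rician-distributed.
#'
#' @param cfg A \code{phantom_config}.
#' @param p An \code{mp2rage_protocol}.
#' @return An object of class \code{volume_set} with elements
#'   \code{inv1_mag}, \code{inv1_phase} (3-D), \code{inv2_mag},
#'   \code{inv2_phase} (4-D, last dimension = echo), \code{b1} (at full or
#'   decimated resolution), \code{tes} (second-block echo times, ms),
#'   \code{truth} (list of t1, t2star, m0, labels arrays), \code{noise_sd}
#'   and the generating \code{config}. The RNG state of the session is left
#'   untouched.
#' @export
generate_phantom <- function(cfg, p) {
  stopifnot(inherits(cfg, "phantom_config"), inherits(p, "mp2rage_protocol"))
  shape <- cfg$grid_shape
  tt <- cfg$tissue_table

  geom <- .phantom_labels(shape, tt)
  labels <- geom$labels
  r2 <- geom$X^2 + geom$Y^2 + geom$Z^2
  b1 <- cfg$b1_range[2] - (cfg$b1_range[2] - cfg$b1_range[1]) * r2 / max(r2)
  freq <- 15 * geom$X + 10 * geom$Y - 8 * geom$X * geom$Z   # Hz, smooth

  t1v <- array(NA_real_, shape); t2v <- array(NA_real_, shape)
  m0v <- array(0, shape)
  for (i in seq_len(nrow(tt))) {
    sel <- labels == tt$label[i]
    t1v[sel] <- tt$t1[i]; t2v[sel] <- tt$t2star[i]; m0v[sel] <- tt$m0[i]
  }

  ne <- length(p$te2)
  s1 <- array(0, shape)
  s2 <- array(0, c(shape, ne))
  sin_a1 <- function(b) sin(deg2rad(b * p$alpha1))
  sin_a2 <- function(b) sin(deg2rad(b * p$alpha2))
  for (i in seq_len(nrow(tt))) {
    sel <- which(labels == tt$label[i])
    if (length(sel) == 0L) next
    bv <- b1[sel]
    m <- .mz_centers(p, tt$t1[i], bv, p$inv_efficiency)
    s1[sel] <- tt$m0[i] * sin_a1(bv) * m$m1 * exp(-p$te1 / tt$t2star[i])
    base2 <- tt$m0[i] * sin_a2(bv) * m$m2
    for (k in seq_len(ne))
      s2[sel + (k - 1L) * prod(shape)] <- base2 * exp(-p$te2[k] / tt$t2star[i])
  }

  # noise scale: white-matter first-echo signal of the second block at B1 = 1
  wm <- tt[tt$name == "WM", ]
  mwm <- .mz_centers(p, wm$t1, 1, p$inv_efficiency)
  ref <- abs(wm$m0 * sin_a2(1) * mwm$m2 * exp(-p$te2[1] / wm$t2star))
  snr <- cfg$snr
  if (is.finite(snr) && snr <= 0) {
    warning("snr <= 0: generating noiseless volumes")
    snr <- Inf
  }
  noise_sd <- if (is.finite(snr)) ref / snr else 0

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(cfg$seed)

  noisy <- function(signal, te) {
    z <- signal * exp(1i * 2 * pi * freq * te / 1000)
    if (noise_sd > 0)
      z <- z + stats::rnorm(length(z), 0, noise_sd) +
        1i * stats::rnorm(length(z), 0, noise_sd)
    z
  }
  z1 <- noisy(s1, p$te1)
  inv1_mag <- array(Mod(z1), shape); inv1_phase <- array(Arg(z1), shape)
  inv2_mag <- array(0, c(shape, ne)); inv2_phase <- array(0, c(shape, ne))
  for (k in seq_len(ne)) {
    zk <- noisy(array(s2[, , , k], shape), p$te2[k])
    inv2_mag[, , , k] <- Mod(zk); inv2_phase[, , , k] <- Arg(zk)
  }

  b1_out <- b1
  if (!is.null(cfg$b1_decimate) && cfg$b1_decimate > 1L)
    b1_out <- .decimate(b1, as.integer(cfg$b1_decimate))

  structure(list(inv1_mag = inv1_mag, inv1_phase = inv1_phase,
                 inv2_mag = inv2_mag, inv2_phase = inv2_phase,
                 b1 = b1_out, tes = p$te2, te1 = p$te1,
                 truth = list(t1 = t1v, t2star = t2v, m0 = m0v,
                              labels = labels),
                 noise_sd = noise_sd, voxel_size = cfg$voxel_size,
                 protocol = p$name, config = cfg),
            class = "volume_set")
}

#' @export
print.volume_set <- function(x, ...) {
  cat(sprintf("synthetic volume set, protocol '%s'\n", x$protocol))
  cat(sprintf("  grid %s at %.2f mm; %d second-block echo(es); noise SD %.4g\n",
              paste(dim(x$inv1_mag), collapse = "x"), x$voxel_size,
              length(x$tes), x$noise_sd))
  invisible(x)
}
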