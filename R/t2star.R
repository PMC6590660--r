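#' Mono-exponential T2* fit of multi-echo magnitude data
#'
#' Fits \code{S(TE) = S0 * exp(-TE / T2*)} per voxel by signal-weighted
#' log-linear least squares (weights = squared signal), the standard fast
#' estimator for multi-echo gradient-echo decay. An optional per-voxel
#' nonlinear refinement is available behind a flag. Echoes whose magnitude
#' falls below three times an estimated background noise SD can be excluded
#' per voxel (at least two echoes are always retained).
#'
#' @param echoes Magnitude data: a matrix (voxels by echoes) or an array
#'   whose last dimension indexes echoes.
#' @param tes Echo times in ms, strictly increasing, one per echo.
#' @param mask Optional logical vector/array selecting voxels to fit; others
#'   are returned invalid.
#' @param noise_sd Optional background noise SD; echoes with signal below
#'   \code{3 * noise_sd} are dropped from the fit voxelwise.
#' @param nonlinear If \code{TRUE}, refine each valid voxel with
#'   Levenberg-type nonlinear least squares started from the log-linear
#'   estimate.
#' @return A list with \code{t2star} (ms), \code{s0} and logical
#'   \code{valid}, shaped like one echo volume. Voxels with a nonpositive
#'   fitted decay rate (non-decaying signal), all-zero signal or fewer than
#'   two usable echoes are invalid (\code{NA} in the maps).
#' @examples
#' s <- outer(c(1, 2), exp(-c(3, 11.5, 20, 28.5) / 26.7))
#' t2star_fit(s, c(3, 11.5, 20, 28.5))$t2star
#' @export
t2star_fit <- function(echoes, tes, mask = NULL, noise_sd = NULL,
                       nonlinear = FALSE) {
  tes <- as.numeric(tes)
  ne <- length(tes)
  if (ne < 2L) stop("at least two echoes are required")
  if (any(diff(tes) <= 0)) stop("'tes' must be strictly increasing")
  dims <- dim(echoes)
  if (is.null(dims)) dims <- c(length(echoes) / ne, ne)
  if (dims[length(dims)] != ne)
    stop("last dimension of 'echoes' (", dims[length(dims)],
         ") does not match length(tes) (", ne, ")")
  vox_dims <- dims[-length(dims)]
  s <- matrix(as.numeric(echoes), ncol = ne)
  nv <- nrow(s)

  w <- s^2                                    # log-linear weights
  w[!is.finite(s) | s <= 0] <- 0
  if (!is.null(noise_sd) && noise_sd > 0) {
    low <- s < 3 * noise_sd
    # keep at least the two strongest echoes per voxel
    keep2 <- t(apply(s, 1L, function(r) rank(-r, ties.method = "first") <= 2L))
    low[keep2] <- FALSE
    w[low] <- 0
  }
  if (!is.null(mask)) w[!as.logical(mask), ] <- 0

  y <- log(ifelse(s > 0, s, NA_real_))
  yw <- ifelse(w > 0, y, 0)
  sw <- rowSums(w)
  swx <- w %*% tes
  swy <- rowSums(w * yw)
  swxx <- w %*% tes^2
  swxy <- (w * yw) %*% tes
  denom <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / denom
  icpt <- (swy - slope * swx) / sw
  n_used <- rowSums(w > 0)
  valid <- is.finite(slope) & slope < 0 & n_used >= 2L & denom > 0
  t2s <- ifelse(valid, -1 / slope, NA_real_)
  s0 <- ifelse(valid, exp(icpt), NA_real_)

  if (nonlinear) {
    for (i in which(valid)) {
      fit <- try(stats::nls(
        si ~ a * exp(-tes / b),
        data = list(si = s[i, ], tes = tes),
        start = list(a = s0[i], b = t2s[i]),
        control = stats::nls.control(warnOnly = TRUE)), silent = TRUE)
      if (!inherits(fit, "try-error")) {
        cf <- stats::coef(fit)
        if (is.finite(cf[["b"]]) && cf[["b"]] > 0) {
          s0[i] <- cf[["a"]]; t2s[i] <- cf[["b"]]
        }
      }
    }
  }

  shape <- function(v) { if (length(vox_dims) > 1L) dim(v) <- vox_dims; v }
  list(t2star = shape(as.numeric(t2s)), s0 = shape(as.numeric(s0)),
       valid = shape(as.logical(valid)))
}
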