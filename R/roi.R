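#' Per-region medians of a quantitative map
#'
#' Summarizes a map over an integer label volume, one row per nonzero label,
#' as done for region-of-interest reporting of quantitative maps.
#'
#' @param map Numeric array or vector.
#' @param labels Integer array of the same length; 0 = unlabelled.
#' @param names Optional data frame with columns \code{label} and \code{name}
#'   (e.g. [default_tissues()]) used to attach region names.
#' @return A data frame with columns \code{label}, \code{name}, \code{n},
#'   \code{median} and \code{iqr}. Labels present in \code{names} but absent
#'   from the volume are reported with \code{n = 0} and \code{NA} statistics.
#' @export
roi_medians <- function(map, labels, names = NULL) {
  if (length(map) != length(labels))
    stop("'map' and 'labels' must have the same length")
  lab <- as.integer(labels)
  present <- sort(unique(lab[lab != 0L]))
  all_labels <- if (is.null(names)) present else
    sort(unique(c(present, as.integer(names$label))))
  rows <- lapply(all_labels, function(L) {
    v <- map[lab == L & is.finite(map)]
    data.frame(label = L,
               n = length(v),
               median = if (length(v)) stats::median(v) else NA_real_,
               iqr = if (length(v)) stats::IQR(v) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out$name <- if (is.null(names)) as.character(out$label) else
    names$name[match(out$label, names$label)]
  out[, c("label", "name", "n", "median", "iqr")]
}

#' Bland-Altman agreement statistics for paired measurements
#'
#' Computes the usual agreement summary between two measurement series: mean
#' difference, reproducibility coefficient (1.96 times the SD of the
#' differences), coefficient of variation (SD of differences relative to the
#' pairwise mean, in percent), squared Pearson correlation, and a
#' Kolmogorov-Smirnov test of the standardized differences against the
#' standard normal (standardizing by the sample mean and SD, so the p-value
#' carries the usual Lilliefors caveat).
#'
#' @param x,y Paired numeric vectors of equal length, at least 3.
#' @return An object of class \code{agreement_stats}: \code{r2},
#'   \code{mean_diff}, \code{rpc}, \code{cv} (percent), \code{ks_p} and
#'   \code{n}. With zero variance in the differences, \code{rpc} and
#'   \code{cv} are 0 and \code{ks_p} is \code{NA} (flagged by
#'   \code{degenerate = TRUE}).
#' @examples
#' set.seed(1)
#' a <- rnorm(50, 1.3, 0.2)
#' bland_altman(a, a + rnorm(50, 0, 0.02))
#' @export
bland_altman <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("at least 3 complete pairs are required")
  d <- x - y
  sd_d <- stats::sd(d)
  mean_diff <- mean(d)
  degenerate <- sd_d == 0
  stats_out <- list(
    r2 = stats::cor(x, y)^2,
    mean_diff = mean_diff,
    rpc = 1.96 * sd_d,
    cv = 100 * sd_d / mean((x + y) / 2),
    ks_p = if (degenerate) NA_real_ else
      suppressWarnings(stats::ks.test((d - mean_diff) / sd_d, "pnorm")$p.value),
    n = length(x),
    degenerate = degenerate
  )
  structure(stats_out, class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("agreement over %d pairs: r2 = %.3f\n", x$n, x$r2))
  cat(sprintf("  mean difference %.4g, RPC %.4g, CV %.2f%%\n",
              x$mean_diff, x$rpc, x$cv))
  cat(sprintf("  KS normality of differences: p = %s%s\n",
              ifelse(is.na(x$ks_p), "NA", sprintf("%.3f", x$ks_p)),
              if (x$degenerate) " (zero-variance differences)" else ""))
  invisible(x)
}
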