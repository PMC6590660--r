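#' Relaxation parameters of one tissue class
#'
#' @param t1 Longitudinal relaxation time in seconds.
#' @param t2star Effective transverse relaxation time in ms.
#' @param m0 Equilibrium magnetization (relative proton density), arbitrary
#'   units.
#' @param label Tissue name.
#' @return An object of class \code{tissue_params}.
#' @examples
#' wm <- tissue_params(1.15, 26.7, 0.70, "WM")
#' @export
tissue_params <- function(t1, t2star, m0 = 1, label = "") {
  if (!is.numeric(t1) || length(t1) != 1L || !is.finite(t1) || t1 <= 0)
    stop("'t1' must be a single positive number (seconds)", call. = FALSE)
  if (!is.numeric(t2star) || length(t2star) != 1L || !is.finite(t2star) || t2star <= 0)
    stop("'t2star' must be a single positive number (ms)", call. = FALSE)
  if (!is.numeric(m0) || length(m0) != 1L || !is.finite(m0) || m0 < 0)
    stop("'m0' must be a single nonnegative number", call. = FALSE)
  structure(list(t1 = t1, t2star = t2star, m0 = m0,
                 label = as.character(label)[1L]),
            class = "tissue_params")
}

#' Default brain tissue table
#'
#' Per-tissue T1 (s) and T2* (ms) used by the synthetic phantom generator:
#' white matter, cortical gray matter, cerebrospinal fluid and six deep
#' gray-matter nuclei, at values typical for healthy adult brain at 7 T.
#' Relative proton densities (m0) are conventional values; CSF T2* is a
#' nominal long value, as the multi-echo fit is not meaningful in free fluid.
#'
#' @return A data frame with columns \code{label} (integer), \code{name},
#'   \code{t1} (s), \code{t2star} (ms) and \code{m0}.
#' @export
default_tissues <- function() {
  data.frame(
    label = 1:9,
    name = c("WM", "GM", "CSF", "caudate", "putamen", "thalamus",
             "red_nucleus", "substantia_nigra", "STN"),
    t1 = c(1.19, 2.00, 4.00, 1.80, 1.63, 1.58, 1.33, 1.38, 1.28),
    t2star = c(26.7, 32.4, 100.0, 27.9, 24.1, 28.1, 16.7, 14.1, 16.4),
    m0 = c(0.70, 0.82, 1.00, 0.82, 0.82, 0.80, 0.75, 0.75, 0.75),
    stringsAsFactors = FALSE
  )
}

#' Tissue triple used by the desk simulations
#'
#' The B1-sensitivity and blurring simulations use a reduced tissue set with
#' round T1 values (WM 1.15 s, GM 1.85 s, CSF 4.0 s) rather than the measured
#' in-vivo medians of [default_tissues()].
#'
#' @return A named list of three \code{tissue_params}: \code{wm}, \code{gm},
#'   \code{csf}.
#' @export
simulation_tissues <- function() {
  list(wm = tissue_params(1.15, 26.7, 0.70, "WM"),
       gm = tissue_params(1.85, 32.4, 0.82, "GM"),
       csf = tissue_params(4.00, 100.0, 1.00, "CSF"))
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf("tissue '%s': T1 %.3f s, T2* %.1f ms, M0 %.2f\n",
              x$label, x$t1, x$t2star, x$m0))
  invisible(x)
}
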