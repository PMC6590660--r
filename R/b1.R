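## Transmit-field (B1+) sensitivity of the UNI contrast.
##
## The UNI intensity depends on T1 but also, residually, on the achieved flip
## angles. Simulating the contrast curve at several relative transmit-field
## factors quantifies that sensitivity, and decoding a B1-shifted intensity
## through the nominal lookup column gives the apparent-T1 bias that remains
## if no transmit-field correction is applied.

#' UNI contrast curves over T1 for several transmit-field factors
#'
#' @param p An \code{mp2rage_protocol}.
#' @param b1_values Relative transmit-field factors; default the conventional
#'   0.8 / 1.0 / 1.2 span.
#' @param t1_axis T1 values in seconds.
#' @param inv_efficiency Inversion efficiency; default 1.
#' @return An object of class \code{contrast_curves}: \code{t1_axis},
#'   \code{b1_values} and the \code{uni} matrix (T1 by B1).
#' @examples
#' cc <- contrast_curves(example_protocol("mp2rage"),
#'                       t1_axis = seq(0.5, 5, by = 0.05))
#' @export
contrast_curves <- function(p, b1_values = c(0.8, 1.0, 1.2),
                            t1_axis = seq(0.5, 5, by = 0.005),
                            inv_efficiency = 1) {
  stopifnot(inherits(p, "mp2rage_protocol"))
  uni <- vapply(b1_values,
                function(b) as.numeric(simulate_uni(p, t1_axis, b, inv_efficiency)),
                numeric(length(t1_axis)))
  structure(list(t1_axis = as.numeric(t1_axis),
                 b1_values = as.numeric(b1_values),
                 uni = matrix(uni, nrow = length(t1_axis)),
                 protocol_name = p$name),
            class = "contrast_curves")
}

#' Spread of UNI intensity across transmit-field factors at a reference T1
#'
#' @param curves A \code{contrast_curves} object.
#' @param t1_ref Reference T1 in seconds, within the curve's T1 axis.
#' @return Max minus min UNI over the curve's B1 values at \code{t1_ref}
#'   (linear interpolation along T1).
#' @export
intensity_range <- function(curves, t1_ref) {
  stopifnot(inherits(curves, "contrast_curves"))
  if (t1_ref < min(curves$t1_axis) || t1_ref > max(curves$t1_axis))
    stop("'t1_ref' outside the curve's T1 axis")
  at_ref <- apply(curves$uni, 2L, function(u)
    stats::approx(curves$t1_axis, u, xout = t1_ref)$y)
  max(at_ref) - min(at_ref)
}

#' Apparent T1 under uncorrected transmit-field deviation
#'
#' Simulates the UNI intensity of a tissue at the actual transmit field and
#' decodes it through the nominal (B1 = 1) lookup column, giving the biased
#' T1 that a correction-free reconstruction would report.
#'
#' @param p An \code{mp2rage_protocol}.
#' @param true_t1 True T1 in seconds (vectorized).
#' @param b1_actual Actual relative transmit field (vectorized; recycled
#'   against \code{true_t1}).
#' @param lut An \code{mp2rage_lut} built for \code{p}; its
#'   inversion-efficiency convention is reused for the forward simulation.
#' @return A list with \code{t1} (apparent T1, seconds) and \code{valid}
#'   (FALSE where the shifted intensity left the nominal monotone branch and
#'   was clamped).
#' @examples
#' p <- example_protocol("mp2rageme")
#' lut <- build_lookup(p, b1_grid = 1)
#' apparent_t1(p, 1.15, c(0.8, 1.2), lut)$t1
#' @export
apparent_t1 <- function(p, true_t1, b1_actual, lut) {
  stopifnot(inherits(p, "mp2rage_protocol"), inherits(lut, "mp2rage_lut"))
  u <- simulate_uni(p, true_t1, b1_actual, inv_efficiency = lut$inv_efficiency)
  res <- lookup_t1(lut, as.numeric(u), b1 = 1)
  list(t1 = res$t1, valid = res$valid)
}

#' UNI contrast between two tissues at nominal transmit
#'
#' @param p An \code{mp2rage_protocol}.
#' @param tissue_a,tissue_b \code{tissue_params} objects.
#' @param inv_efficiency Inversion efficiency; default 1.
#' @return Absolute UNI difference between the two tissues at B1 = 1.
#' @examples
#' gm <- tissue_params(1.85, 32.4, 0.82, "GM")
#' csf <- tissue_params(4.0, 100, 1.0, "CSF")
#' contrast_metrics(example_protocol("mp2rage"), gm, csf)
#' @export
contrast_metrics <- function(p, tissue_a, tissue_b, inv_efficiency = 1) {
  stopifnot(inherits(tissue_a, "tissue_params"),
            inherits(tissue_b, "tissue_params"))
  u <- simulate_uni(p, c(tissue_a$t1, tissue_b$t1), 1, inv_efficiency)
  abs(u[1] - u[2])
}
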