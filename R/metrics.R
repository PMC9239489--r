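#' Relative root-mean-square error
#'
#' `RRMSE = ||x - z||_2 / ||z||_2` between a test image `x` and the
#' reference `z` (default), a scale-free error fixed for a given ground
#' truth. `variant = "printed"` instead normalises by the plain pixel sum
#' of the test image, `sqrt(sum((x - z)^2)) / sum(x)`, an alternative
#' normalisation sometimes seen in the literature.
#'
#' @param test,reference numeric matrices of identical shape.
#' @param variant `"reference_norm"` (default) or `"printed"`.
#' @return Nonnegative scalar; 0 iff the images are identical.
#' @examples
#' z <- make_phantom(32, "disk")
#' rrmse(2 * z, z)  # 1
#' @export
rrmse <- function(test, reference, variant = c("reference_norm", "printed")) {
  variant <- match.arg(variant)
  if (!all(dim(test) == dim(reference)))
    stop("test and reference must have identical shapes")
  err <- sqrt(sum((test - reference)^2))
  denom <- if (variant == "reference_norm") sqrt(sum(reference^2))
           else sum(test)
  if (denom == 0) stop("zero normalisation; reference (or test sum) is zero")
  err / denom
}

#' Global structural similarity index
#'
#' Single-window SSIM over the whole image:
#' `(2*mu_x*mu_z + c1) * (2*sigma_xz + c2) /
#'  ((mu_x^2 + mu_z^2 + c1) * (sigma_x^2 + sigma_z^2 + c2))`
#' with `c1 = (k1*s)^2`, `c2 = (k2*s)^2`. Moments use population (1/N)
#' normalisation. The dynamic range `s` defaults to
#' `max(reference) - min(reference)`; `dynamic_range = "pooled"` uses the
#' range of both images jointly, which makes the index symmetric in its
#' arguments.
#'
#' @param test,reference numeric matrices of identical shape.
#' @param k1,k2 stabilisation constants (defaults 0.01 and 0.03).
#' @param dynamic_range `"reference"` (default) or `"pooled"`.
#' @return Scalar `<= 1`; exactly 1 for identical images.
#' @export
ssim_global <- function(test, reference, k1 = 0.01, k2 = 0.03,
                        dynamic_range = c("reference", "pooled")) {
  dynamic_range <- match.arg(dynamic_range)
  if (!all(dim(test) == dim(reference)))
    stop("test and reference must have identical shapes")
  x <- as.vector(test); z <- as.vector(reference)
  if (identical(x, z)) return(1)
  s <- if (dynamic_range == "reference") diff(range(z))
       else diff(range(c(x, z)))
  if (s == 0) s <- 1   # constant reference: fall back to unit range
  c1 <- (k1 * s)^2; c2 <- (k2 * s)^2
  mx <- mean(x); mz <- mean(z)
  vx <- mean((x - mx)^2); vz <- mean((z - mz)^2)
  cxz <- mean((x - mx) * (z - mz))
  (2 * mx * mz + c1) * (2 * cxz + c2) /
    ((mx^2 + mz^2 + c1) * (vx + vz + c2))
}

#' Radii of the rings produced by given detector bins
#'
#' A constant error on detector bin `r` reconstructs to a circle of radius
#' `|s_r|` around the rotation centre, where `s_r` is the bin's signed
#' detector offset.
#'
#' @param geometry a [ct_geometry()].
#' @param bins detector bin indices.
#' @return Numeric vector of radii in pixel units.
#' @export
ring_radii <- function(geometry, bins) {
  abs((bins - (geometry$n_bins + 1) / 2) * geometry$detector_spacing)
}

#' Maximum reconstruction error along rings
#'
#' For each requested radius, the maximum absolute difference between test
#' and reference over the annulus of pixels within `width` of that radius;
#' used to quantify residual ring artifacts at the radii of known bad
#' detector bins. The attribute `"background"` carries the median absolute
#' error over all pixels outside every annulus, a reference level for
#' deciding whether a ring stands out.
#'
#' @param test,reference numeric `n x n` matrices.
#' @param radii ring radii in pixel units (see [ring_radii()]).
#' @param width annulus half-width in pixels.
#' @return Numeric vector of per-radius maxima with attribute
#'   `"background"`.
#' @export
radial_max_error <- function(test, reference, radii, width = 1.5) {
  if (!all(dim(test) == dim(reference)))
    stop("test and reference must have identical shapes")
  n <- nrow(test)
  ctr <- (n + 1) / 2
  xs <- seq_len(n) - ctr
  rad <- sqrt(outer(xs^2, xs^2, "+"))
  err <- abs(test - reference)
  inside_any <- matrix(FALSE, n, n)
  out <- vapply(radii, function(r0) {
    ann <- abs(rad - r0) <= width
    inside_any <<- inside_any | ann
    if (!any(ann)) return(NA_real_)
    max(err[ann])
  }, numeric(1))
  names(out) <- signif(radii, 4)
  attr(out, "background") <- stats::median(err[!inside_any])
  out
}
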