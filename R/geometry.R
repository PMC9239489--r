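#' Parallel-beam projection geometry
#'
#' Defines the acquisition geometry that ties an `n x n` attenuation image to
#' its sinogram: the number of detector bins per view, the number of views,
#' and the angular range they uniformly cover. View angles are measured from
#' the x-axis, counter-clockwise, at the left edge of each uniform interval
#' (`angle_k = k * range / n_angles`, `k = 0, ..., n_angles - 1`). The
#' detector array is centred on the rotation axis; detector spacing and pixel
#' size are expressed in the same (pixel) units.
#'
#' @param n_pixels side length of the square image (image has `n_pixels^2`
#'   unknowns).
#' @param n_bins number of detector bins per view (`R`).
#' @param n_angles number of projection angles (`Theta`).
#' @param angular_range total angular coverage in degrees, 180 or 360.
#' @param detector_spacing detector bin pitch in pixel units (default 1).
#' @return An object of class `ct_geometry`: a list with the fields above plus
#'   `angles` (radians, strictly increasing) and an internal cache for the
#'   system matrix.
#' @examples
#' g <- ct_geometry(64, n_bins = 95, n_angles = 60)
#' g$angles[1:3]
#' @seealso [forward_project()], [back_project()], [fbp_reconstruct()],
#'   [system_matrix()]
#' @export
ct_geometry <- function(n_pixels, n_bins = n_pixels, n_angles,
                        angular_range = 360, detector_spacing = 1) {
  if (n_pixels < 1 || n_bins < 1 || n_angles < 1)
    stop("all geometry dimensions must be positive integers")
  if (!angular_range %in% c(180, 360))
    stop("angular_range must be 180 or 360 degrees")
  if (detector_spacing <= 0)
    stop("detector_spacing must be positive")
  g <- list(
    n_pixels = as.integer(n_pixels),
    n_bins = as.integer(n_bins),
    n_angles = as.integer(n_angles),
    angular_range = angular_range,
    detector_spacing = detector_spacing,
    angles = (seq_len(n_angles) - 1) * (angular_range * pi / 180) / n_angles,
    cache = new.env(parent = emptyenv())
  )
  class(g) <- "ct_geometry"
  g
}

#' @export
print.ct_geometry <- function(x, ...) {
  cat(sprintf(
    "Parallel-beam CT geometry: %d x %d image, %d bins x %d angles over %g deg\n",
    x$n_pixels, x$n_pixels, x$n_bins, x$n_angles, x$angular_range))
  invisible(x)
}

check_image <- function(image, geometry) {
  if (!is.matrix(image) || any(dim(image) != geometry$n_pixels))
    stop(sprintf("image must be a %d x %d matrix matching the geometry",
                 geometry$n_pixels, geometry$n_pixels))
  if (!all(is.finite(image))) stop("image contains non-finite values")
  invisible(TRUE)
}

check_sinogram <- function(sinogram, geometry) {
  if (!is.matrix(sinogram) ||
      nrow(sinogram) != geometry$n_bins || ncol(sinogram) != geometry$n_angles)
    stop(sprintf("sinogram must be a %d x %d (bins x angles) matrix",
                 geometry$n_bins, geometry$n_angles))
  if (!all(is.finite(sinogram))) stop("sinogram contains non-finite values")
  invisible(TRUE)
}

#' Sparse system matrix for a parallel-beam geometry
#'
#' Builds (and caches on the geometry object) the `M x N` system matrix `A`
#' whose rows are the discretised line integrals of every (bin, angle) pair,
#' with `M = n_bins * n_angles` and `N = n_pixels^2`. Rays follow Joseph's
#' method: each ray is stepped along its dominant axis one pixel row (or
#' column) at a time, the image is linearly interpolated across the other
#' axis, and samples are weighted by the step length along the ray, so row
#' sums approximate intersection lengths. The backprojector used by the
#' solver is the exact algebraic transpose `t(A)`, which makes the
#' gradient-descent image update an exact gradient.
#'
#' Sinograms are vectorised column-major (bin index fastest), images
#' column-major with the first index along x.
#'
#' @param geometry a [ct_geometry()].
#' @return A `dgCMatrix` of dimension `(n_bins * n_angles) x n_pixels^2`.
#' @export
system_matrix <- function(geometry) {
  stopifnot(is(geometry, "ct_geometry"))
  if (!is.null(geometry$cache$A)) return(geometry$cache$A)
  n <- geometry$n_pixels
  R <- geometry$n_bins
  Th <- geometry$n_angles
  ds <- geometry$detector_spacing
  s <- (seq_len(R) - (R + 1) / 2) * ds
  ctr <- (n + 1) / 2
  ii <- jj <- xx <- vector("list", Th)
  for (t in seq_len(Th)) {
    ca <- cos(geometry$angles[t]); sa <- sin(geometry$angles[t])
    # ray for bin r: { s_r * (ca, sa) + t * (-sa, ca) }; step along the
    # dominant component of the ray direction (-sa, ca)
    if (abs(ca) >= abs(sa)) {
      axis_pos <- seq_len(n) - ctr                  # y of each pixel row
      cross <- outer(s, axis_pos * sa, function(a, b) (a - b) / ca) + ctr
      w <- 1 / abs(ca)
      fixed_idx <- rep(seq_len(n), each = R)        # y index
      col_of <- function(i, fixed) i + (fixed - 1L) * n
    } else {
      axis_pos <- seq_len(n) - ctr                  # x of each pixel column
      cross <- outer(s, axis_pos * ca, function(a, b) (a - b) / sa) + ctr
      w <- 1 / abs(sa)
      fixed_idx <- rep(seq_len(n), each = R)        # x index
      col_of <- function(i, fixed) fixed + (i - 1L) * n
    }
    rows <- rep(seq_len(R), times = n) + (t - 1L) * R
    i0 <- floor(cross)
    fr <- as.vector(cross - i0)
    i0 <- as.vector(i0)
    k0 <- i0 >= 1 & i0 <= n
    k1 <- i0 + 1 >= 1 & i0 + 1 <= n
    ii[[t]] <- c(rows[k0], rows[k1])
    jj[[t]] <- c(col_of(i0[k0], fixed_idx[k0]), col_of(i0[k1] + 1L, fixed_idx[k1]))
    xx[[t]] <- c((1 - fr[k0]) * w, fr[k1] * w)
  }
  A <- sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                    dims = c(R * Th, n * n))
  geometry$cache$A <- A
  A
}

#' Squared spectral norm of the system matrix
#'
#' Estimates `||A||_2^2` (the Lipschitz constant of the least-squares
#' gradient) by deterministic power iteration on `A'A`; cached on the
#' geometry. Used by the automatic step-size rule of [ring_recon()].
#'
#' @param geometry a [ct_geometry()].
#' @param iters number of power iterations.
#' @return A scalar, the largest eigenvalue of `A'A` (to power-iteration
#'   accuracy; an over-estimate is approached from below, so the solver
#'   multiplies by a small safety margin).
#' @export
operator_norm_sq <- function(geometry, iters = 30) {
  if (!is.null(geometry$cache$normA2)) return(geometry$cache$normA2)
  A <- system_matrix(geometry)
  v <- rep(1, ncol(A))
  nv <- 1
  for (k in seq_len(iters)) {
    v <- as.vector(crossprod(A, A %*% v))
    nv <- sqrt(sum(v^2))
    v <- v / nv
  }
  geometry$cache$normA2 <- nv
  nv
}

#' Forward projection (Radon transform)
#'
#' Applies the system matrix to an image, producing its parallel-beam
#' sinogram of log-attenuation line integrals. Linear in the image.
#'
#' @param image `n x n` numeric matrix of attenuation coefficients.
#' @param geometry a [ct_geometry()] with matching `n_pixels`.
#' @return A `n_bins x n_angles` sinogram matrix.
#' @examples
#' g <- ct_geometry(32, 47, 24)
#' sino <- forward_project(make_phantom(32, "disk"), g)
#' dim(sino)
#' @export
forward_project <- function(image, geometry) {
  check_image(image, geometry)
  A <- system_matrix(geometry)
  matrix(as.vector(A %*% as.vector(image)),
         geometry$n_bins, geometry$n_angles)
}

#' Backprojection (adjoint of the forward projector)
#'
#' Applies the exact transpose of the system matrix to a sinogram. This is
#' the unfiltered adjoint used inside the solver's gradient, not filtered
#' back-projection; see [fbp_reconstruct()] for the latter.
#'
#' @param sinogram `n_bins x n_angles` numeric matrix.
#' @param geometry a [ct_geometry()].
#' @return An `n x n` image matrix equal to `t(A) %*% sinogram`.
#' @export
back_project <- function(sinogram, geometry) {
  check_sinogram(sinogram, geometry)
  A <- system_matrix(geometry)
  n <- geometry$n_pixels
  matrix(as.vector(crossprod(A, as.vector(sinogram))), n, n)
}

#' Filtered back-projection reconstruction
#'
#' Standard FBP: each view is ramp-filtered (Ram-Lak, applied in the
#' frequency domain after zero-padding to the next power of two at least
#' `2 * n_bins`), then backprojected pixel-driven with linear interpolation
#' along the detector. The output is scaled by `pi / (2 * n_angles)` per the
#' discretised inverse Radon formula; with a 360-degree range opposing views
#' average, so the same scaling keeps the intensity scale consistent with a
#' 180-degree acquisition.
#'
#' @param sinogram `n_bins x n_angles` numeric matrix.
#' @param geometry a [ct_geometry()]; needs `n_angles >= 2`.
#' @return An `n x n` reconstructed image.
#' @examples
#' g <- ct_geometry(64, 95, 90, angular_range = 180)
#' ph <- make_phantom(64, "disk")
#' rec <- fbp_reconstruct(forward_project(ph, g), g)
#' rrmse(rec, ph)
#' @export
fbp_reconstruct <- function(sinogram, geometry) {
  check_sinogram(sinogram, geometry)
  if (geometry$n_angles < 2)
    stop("FBP needs at least 2 projection angles")
  n <- geometry$n_pixels
  R <- geometry$n_bins
  Th <- geometry$n_angles
  ds <- geometry$detector_spacing
  npad <- 2^ceiling(log2(2 * R))
  freq <- c(seq(0, npad / 2), seq(-npad / 2 + 1, -1)) / npad
  filt <- 2 * abs(freq)
  P <- rbind(sinogram, matrix(0, npad - R, Th))
  Q <- Re(mvfft(mvfft(P) * filt, inverse = TRUE)) / npad
  Q <- Q[seq_len(R), , drop = FALSE] / ds
  ctr <- (n + 1) / 2
  xs <- seq_len(n) - ctr
  X <- matrix(rep(xs, n), n, n)
  Y <- matrix(rep(xs, each = n), n, n)
  rec <- matrix(0, n, n)
  for (t in seq_len(Th)) {
    sq <- (X * cos(geometry$angles[t]) + Y * sin(geometry$angles[t])) / ds +
      (R + 1) / 2
    i0 <- floor(sq)
    fr <- sq - i0
    ok0 <- i0 >= 1 & i0 <= R
    ok1 <- i0 + 1 >= 1 & i0 + 1 <= R
    v <- matrix(0, n, n)
    v[ok0] <- v[ok0] + (1 - fr[ok0]) * Q[i0[ok0], t]
    v[ok1] <- v[ok1] + fr[ok1] * Q[i0[ok1] + 1, t]
    rec <- rec + v
  }
  rec * pi / (2 * Th)
}
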