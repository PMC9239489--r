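# Modified Shepp-Logan ellipse set (Toft's parameterisation):
# columns: additive intensity, semi-axes a, b, centre x0, y0, rotation (deg)
shepp_logan_ellipses <- matrix(c(
   1.0,  0.69,   0.92,   0,     0,      0,
  -0.8,  0.6624, 0.874,  0,    -0.0184, 0,
  -0.2,  0.11,   0.31,   0.22,  0,    -18,
  -0.2,  0.16,   0.41,  -0.22,  0,     18,
   0.1,  0.21,   0.25,   0,     0.35,   0,
   0.1,  0.046,  0.046,  0,     0.1,    0,
   0.1,  0.046,  0.046,  0,    -0.1,    0,
   0.1,  0.046,  0.023, -0.08, -0.605,  0,
   0.1,  0.023,  0.023,  0,    -0.606,  0,
   0.1,  0.023,  0.046,  0.06, -0.605,  0), ncol = 6, byrow = TRUE)

# indicator accumulation of rotated ellipses on coordinate grids in [-1, 1]
add_ellipses <- function(X, Y, tab) {
  img <- matrix(0, nrow(X), ncol(X))
  for (e in seq_len(nrow(tab))) {
    th <- tab[e, 6] * pi / 180
    xr <- (X - tab[e, 4]) * cos(th) + (Y - tab[e, 5]) * sin(th)
    yr <- -(X - tab[e, 4]) * sin(th) + (Y - tab[e, 5]) * cos(th)
    inside <- (xr / tab[e, 2])^2 + (yr / tab[e, 3])^2 <= 1
    img[inside] <- img[inside] + tab[e, 1]
  }
  img
}

#' Deterministic test phantoms
#'
#' Builds an `n x n` attenuation image with values in `[0, 1]`:
#' \describe{
#'   \item{disk}{unit disk of radius `0.4 * n` pixels, centred.}
#'   \item{shepp_logan}{the modified Shepp-Logan head phantom (standard
#'     ten-ellipse parameter set).}
#'   \item{chest_like}{a synthetic thorax stand-in: a soft-tissue body
#'     ellipse (0.30), two low-attenuation lung ellipses (0.05), four
#'     high-attenuation rib-like arc segments (0.70) and a heart ellipse
#'     (0.45). Edges are anti-aliased by 2x2 supersampling so boundary
#'     pixels carry partial-volume values, as in real sampled CT slices.}
#' }
#' All phantoms are deterministic (no randomness).
#'
#' @param n side length in pixels (>= 16).
#' @param kind phantom family.
#' @return An `n x n` numeric matrix.
#' @examples
#' ph <- make_phantom(64, "chest_like")
#' range(ph)
#' @export
make_phantom <- function(n, kind = c("chest_like", "disk", "shepp_logan")) {
  kind <- match.arg(kind)
  if (n < 16) stop("n must be >= 16")
  grid <- function(m) {
    xs <- (seq_len(m) - (m + 1) / 2) / (m / 2)
    list(X = matrix(rep(xs, m), m, m), Y = matrix(rep(xs, each = m), m, m))
  }
  if (kind == "disk") {
    gctr <- grid(n)
    return((gctr$X^2 + gctr$Y^2 <= 0.8^2) * 1)   # radius 0.4 * n pixels
  }
  if (kind == "shepp_logan") {
    gctr <- grid(n)
    img <- add_ellipses(gctr$X, gctr$Y, shepp_logan_ellipses)
    return(pmin(pmax(img, 0), 1))
  }
  # chest_like, 2x supersampled then block-averaged
  ss <- 2L
  N <- n * ss
  gctr <- grid(N)
  X <- gctr$X; Y <- gctr$Y
  img <- matrix(0, N, N)
  img[(X / 0.85)^2 + (Y / 0.65)^2 <= 1] <- 0.30
  img[((X + 0.38) / 0.30)^2 + (Y / 0.42)^2 <= 1] <- 0.05
  img[((X - 0.38) / 0.30)^2 + (Y / 0.42)^2 <= 1] <- 0.05
  rib <- ((X / 0.80)^2 + (Y / 0.60)^2 <= 1) &
    ((X / 0.74)^2 + (Y / 0.54)^2 > 1)
  arcs <- (floor((atan2(Y, X) + pi) / (pi / 4)) %% 2) == 0
  img[rib & arcs] <- 0.70
  img[((X - 0.05) / 0.22)^2 + ((Y + 0.15) / 0.26)^2 <= 1] <- 0.45
  out <- matrix(0, n, n)
  for (i in seq_len(ss)) for (j in seq_len(ss))
    out <- out + img[seq(i, N, ss), seq(j, N, ss)]
  out / ss^2
}

#' Detector-bin sensitivity error model
#'
#' Describes which detector bins are miscalibrated and how: isolated bins
#' (`adjacency = "non_adjacent"`) or runs of up to `max_run_width`
#' consecutive bins (`"adjacent_runs"`, giving thick rings), with offsets
#' either constant over all angles (`angular_mode = "constant"`, the pure
#' detector-sensitivity case) or modulated per angle
#' (`"varying"`). Offsets act additively in the log-sinogram domain,
#' matching the additive decomposition `A x = b + lambda`; the default
#' per-bin magnitude is drawn uniformly from 2-10 percent of the clean sinogram's
#' maximum with random sign, at corruption time. Bad bins are placed away
#' from the outermost 5 percent of the detector so the rings fall inside the
#' object. Everything is deterministic given `seed`.
#'
#' @param n_bins number of detector bins of the target geometry.
#' @param n_bad number of bad bins (non_adjacent) or bad runs
#'   (adjacent_runs); default 2.5 percent of `n_bins` (at least 3).
#' @param adjacency `"non_adjacent"` or `"adjacent_runs"`.
#' @param max_run_width maximum consecutive-bin run width (default 3).
#' @param angular_mode `"constant"` or `"varying"`.
#' @param magnitude optional vector of absolute per-bin offsets (recycled);
#'   if `NULL`, magnitudes are relative, drawn from `rel_magnitude`.
#' @param rel_magnitude range of |offset| relative to `max(sinogram)` used
#'   when `magnitude` is `NULL`.
#' @param varying_law function `(magnitude_r, theta_index, n_angles)` giving
#'   the per-angle offset when `angular_mode = "varying"`; default
#'   `m * (1 + 0.5 * sin(2 * pi * theta / n_angles))`, a smooth bounded
#'   modulation in `[0.5, 1.5] * m`.
#' @param edge_exclude fraction of bins excluded at each detector edge.
#' @param seed integer seed driving bin placement, magnitudes and signs.
#' @return An object of class `ring_error_model` with fields `bad_bins`
#'   (all affected bin indices) and `bin_magnitude` (relative or absolute
#'   per affected bin).
#' @seealso [corrupt_sinogram()]
#' @export
ring_error_model <- function(n_bins, n_bad = NULL,
                             adjacency = c("non_adjacent", "adjacent_runs"),
                             max_run_width = 3,
                             angular_mode = c("constant", "varying"),
                             magnitude = NULL,
                             rel_magnitude = c(0.02, 0.10),
                             varying_law = NULL,
                             edge_exclude = 0.05, seed = 1) {
  adjacency <- match.arg(adjacency)
  angular_mode <- match.arg(angular_mode)
  # defaults keep the affected-bin fraction at or below 5% of the detector
  if (is.null(n_bad))
    n_bad <- if (adjacency == "non_adjacent") max(3L, round(0.025 * n_bins))
             else max(2L, round(0.015 * n_bins))
  if (n_bad == 0) {
    return(structure(list(bad_bins = integer(0), bin_magnitude = numeric(0),
                          relative = is.null(magnitude),
                          adjacency = adjacency,
                          max_run_width = max_run_width,
                          angular_mode = angular_mode,
                          varying_law = varying_law, seed = seed),
                     class = "ring_error_model"))
  }
  lo <- ceiling(edge_exclude * n_bins) + 1L
  hi <- floor((1 - edge_exclude) * n_bins)
  if (hi - lo + 1 < n_bad * (max_run_width + 1))
    stop("too many bad bins for the detector size")
  rs <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    if (adjacency == "non_adjacent") {
      repeat {
        bins <- sort(sample(lo:hi, n_bad))
        if (n_bad == 1 || min(diff(bins)) >= 2) break
      }
      runs <- as.list(bins)
    } else {
      widths <- sample(max_run_width, n_bad, replace = TRUE)
      repeat {
        starts <- sort(sample(lo:(hi - max_run_width + 1), n_bad))
        runs <- Map(function(s, w) s:(s + w - 1), starts, widths)
        all_bins <- unlist(runs)
        if (!anyDuplicated(all_bins) &&
            (n_bad == 1 || min(diff(sapply(runs, max))) > max_run_width))
          break
      }
    }
    bins <- sort(unique(unlist(runs)))
    magr <- if (is.null(magnitude)) {
      runif(length(runs), rel_magnitude[1], rel_magnitude[2]) *
        sample(c(-1, 1), length(runs), replace = TRUE)
    } else rep_len(magnitude, length(runs))
    # every bin of a run shares its run's magnitude
    bin_mag <- numeric(length(bins))
    for (i in seq_along(runs))
      bin_mag[match(runs[[i]], bins)] <- magr[i]
    list(bins = bins, bin_mag = bin_mag)
  })
  structure(list(bad_bins = rs$bins, bin_magnitude = rs$bin_mag,
                 relative = is.null(magnitude),
                 adjacency = adjacency, max_run_width = max_run_width,
                 angular_mode = angular_mode,
                 varying_law = varying_law, seed = seed),
            class = "ring_error_model")
}

#' @export
print.ring_error_model <- function(x, ...) {
  cat(sprintf("Ring error model: %d bad bins (%s, %s offsets)\n",
              length(x$bad_bins), x$adjacency, x$angular_mode))
  cat("  bins:", x$bad_bins, "\n")
  invisible(x)
}

#' Corrupt a sinogram with detector-bin sensitivity errors
#'
#' Applies a [ring_error_model()] to a clean sinogram. Under the model
#' `A x = b + lambda` the measured data is `b = A x - lambda`, so the
#' corrupted sinogram is `clean - lambda_true`; a solver run on the result
#' recovers `lambda` approximately equal to `lambda_true`. Relative
#' magnitudes are resolved against `max(clean)` here.
#'
#' @param clean `n_bins x n_angles` clean sinogram.
#' @param model a [ring_error_model()].
#' @return A list with `sinogram` (corrupted) and `lambda_true`
#'   (bins x angles; zero outside bad bins; constant per bin across angles
#'   when `angular_mode = "constant"`).
#' @examples
#' g <- ct_geometry(32, 47, 24)
#' b <- forward_project(make_phantom(32, "disk"), g)
#' cor <- corrupt_sinogram(b, ring_error_model(47, n_bad = 3, seed = 2))
#' which(rowSums(abs(cor$lambda_true)) > 0)
#' @export
corrupt_sinogram <- function(clean, model) {
  stopifnot(is(model, "ring_error_model"))
  R <- nrow(clean); Th <- ncol(clean)
  if (any(model$bad_bins < 1 | model$bad_bins > R))
    stop("bad bins outside the detector range")
  mag <- model$bin_magnitude
  if (model$relative) mag <- mag * max(clean)
  lambda_true <- matrix(0, R, Th)
  if (model$angular_mode == "constant") {
    lambda_true[model$bad_bins, ] <- mag
  } else {
    law <- model$varying_law
    if (is.null(law))
      law <- function(m, theta, n_angles)
        m * (1 + 0.5 * sin(2 * pi * theta / n_angles))
    for (i in seq_along(model$bad_bins))
      lambda_true[model$bad_bins[i], ] <- law(mag[i], seq_len(Th), Th)
  }
  list(sinogram = clean - lambda_true, lambda_true = lambda_true)
}

#' Poisson counting noise in the projection domain
#'
#' Converts each log-attenuation value `p` to an expected photon count
#' `b = b0 * exp(-p)`, draws `b~ ~ Poisson(b)` and returns the noisy
#' log-attenuation `g = -log(b~ / b0)`. Zero counts are clamped to 1 before
#' the log (negligible at the default `b0 = 1e6`). For expected counts
#' above `1e8` the Poisson draw is replaced by its Gaussian limit
#' (`rpois` cannot represent such means), which is indistinguishable at
#' that count level. Reproducible given `seed`.
#'
#' @param sinogram matrix of nonnegative log-attenuation values.
#' @param b0 mean unattenuated photon count per bin (> 0).
#' @param seed integer seed.
#' @return Noisy sinogram of the same shape.
#' @export
add_poisson_noise <- function(sinogram, b0 = 1e6, seed = 1) {
  if (b0 <= 0) stop("b0 must be > 0")
  # slightly negative log-attenuation (e.g. a corrupted air bin) is allowed:
  # the expected count is then simply above b0
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  mean_counts <- b0 * exp(-as.vector(sinogram))
  counts <- numeric(length(mean_counts))
  big <- mean_counts > 1e8
  counts[!big] <- rpois(sum(!big), mean_counts[!big])
  if (any(big))
    counts[big] <- round(rnorm(sum(big), mean_counts[big],
                               sqrt(mean_counts[big])))
  counts <- pmax(counts, 1)
  matrix(-log(counts / b0), nrow(sinogram), ncol(sinogram))
}

#' Reference simulation study cases
#'
#' Reproduces the simulation protocol at a chosen scale: a chest-like
#' phantom is forward projected in a 360-degree parallel-beam geometry and
#' corrupted by one of three detector-error setups:
#' \describe{
#'   \item{1}{non-adjacent bad bins, offsets constant over angles.}
#'   \item{2}{adjacent runs of up to 3 bins, constant over angles (thick
#'     rings).}
#'   \item{3}{adjacent runs, offsets varying with angle.}
#'   \item{noisy}{case 1 plus Poisson noise at `b0` counts/bin.}
#' }
#' The geometry defaults scale the reference setup (512 x 512 image,
#' 512 bins x 1000 angles) proportionally to `n`.
#'
#' @param case `1`, `2`, `3` or `"noisy"`.
#' @param n image side length (>= 64).
#' @param n_bins,n_angles optional geometry overrides; defaults `n` and
#'   `round(n * 1000 / 512)`.
#' @param n_bad number of bad bins/runs (default as in
#'   [ring_error_model()]).
#' @param b0 photon count for the noisy case.
#' @param seed integer seed for bin placement, magnitudes and noise.
#' @return A list with `phantom`, `geometry`, `clean`, `corrupted`,
#'   `lambda_true` and the `model` used.
#' @examples
#' sc <- make_study_case(1, n = 64, seed = 3)
#' which(rowSums(abs(sc$lambda_true)) != 0)
#' @export
make_study_case <- function(case = c("1", "2", "3", "noisy"), n = 128,
                            n_bins = NULL, n_angles = NULL, n_bad = NULL,
                            b0 = 1e6, seed = 1) {
  case <- match.arg(as.character(case), c("1", "2", "3", "noisy"))
  if (n < 64) stop("n must be >= 64")
  if (is.null(n_bins)) n_bins <- n
  if (is.null(n_angles)) n_angles <- round(n * 1000 / 512)
  geometry <- ct_geometry(n, n_bins, n_angles, angular_range = 360)
  phantom <- make_phantom(n, "chest_like")
  clean <- forward_project(phantom, geometry)
  model <- ring_error_model(
    n_bins, n_bad = n_bad,
    adjacency = if (case %in% c("2", "3")) "adjacent_runs" else "non_adjacent",
    angular_mode = if (case == "3") "varying" else "constant",
    seed = seed)
  cor <- corrupt_sinogram(clean, model)
  corrupted <- cor$sinogram
  if (case == "noisy")
    corrupted <- add_poisson_noise(corrupted, b0 = b0, seed = seed + 1)
  list(phantom = phantom, geometry = geometry, clean = clean,
       corrupted = corrupted, lambda_true = cor$lambda_true, model = model)
}
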