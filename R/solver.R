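#' Solver configuration
#'
#' Collects every tunable of the ring-elimination ADMM into one object.
#' Defaults follow the reference parameterisation of the noise-free
#' simulation study (`L = 2`, `K = 2000`, `alpha = 0.125`, `rho = 0.004`,
#' `delta = 0.092`, `beta_prime = 15`, `eta = 0.001`), except that `alpha`
#' defaults to an automatic spectral rule (see Details) because a fixed
#' step size only transfers between geometries if it respects
#' `alpha * rho * ||A||^2 < 2`.
#'
#' @details With `alpha = NULL` the step is set to
#'   `1.9 / (rho * ||A||^2)` (`1.9 / ||A||^2` for the l2 baseline), using
#'   the power-iteration estimate from [operator_norm_sq()]; this is just
#'   below the stability bound `2 / (rho * ||A||^2)` of gradient descent on
#'   the quadratic image subproblem.
#'
#' @param norm data-fidelity norm on the imperfect component: `"l1"`,
#'   `"l0"`, `"hl1"` (Huber-l1), `"hl0"` (Huber-l0), or `"l2"` for the
#'   plain least-squares baseline (no sparse component is estimated).
#' @param rho ADMM penalty parameter (> 0); the prox weight is
#'   `mu = 1 / rho`.
#' @param delta Huber transition point for `"hl1"`/`"hl0"`.
#' @param alpha gradient-descent step size, or `NULL` for the spectral rule.
#' @param beta_prime smoothing strength `beta' = alpha * beta` applied to
#'   the gradient of the Huber MRF penalty inside each GD step; 0 disables
#'   smoothing.
#' @param eta edge threshold of the smoothing penalty.
#' @param weights neighbour weighting of the smoothing penalty, see
#'   [smoothing_value()].
#' @param K number of outer (ADMM) iterations.
#' @param L number of inner gradient-descent steps per outer iteration.
#' @param constrained if `TRUE`, the angular-constrained variant: the error
#'   component is forced identical across angles for each detector bin and
#'   updated by the prox of the angle-averaged residual.
#' @param init `"zero"` (default) or `"fbp"`: start the image at zero or at
#'   the filtered back-projection of the measured sinogram.
#' @param init_image,init_lambda,init_multiplier optional explicit initial
#'   values (matrices of the right shape); `init_image` overrides `init`.
#' @param tol optional early-stopping tolerance on the relative primal
#'   residual `||lambda - Ax + b|| / ||b||`; `NULL` (default) runs all `K`
#'   iterations as in the reference algorithm.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(norm = c("l1", "l0", "hl1", "hl0", "l2"),
                          rho = 0.004, delta = 0.092, alpha = NULL,
                          beta_prime = 0, eta = 0.001,
                          weights = "inverse_distance",
                          K = 2000, L = 2, constrained = FALSE,
                          init = c("zero", "fbp"), tol = NULL,
                          init_image = NULL, init_lambda = NULL,
                          init_multiplier = NULL) {
  norm <- match.arg(norm)
  init <- match.arg(init)
  if (rho <= 0) stop("rho must be > 0")
  if (!is.null(alpha) && alpha <= 0) stop("alpha must be > 0")
  if (K < 1 || L < 1) stop("K and L must be >= 1")
  if (beta_prime < 0) stop("beta_prime must be >= 0")
  if (norm %in% c("hl1", "hl0") && delta <= 0) stop("delta must be > 0")
  if (eta <= 0) stop("eta must be > 0")
  structure(list(norm = norm, rho = rho, delta = delta, alpha = alpha,
                 beta_prime = beta_prime, eta = eta, weights = weights,
                 K = as.integer(K), L = as.integer(L),
                 constrained = isTRUE(constrained), init = init, tol = tol,
                 init_image = init_image, init_lambda = init_lambda,
                 init_multiplier = init_multiplier),
            class = "solver_config")
}

# canonical algorithm label, e.g. "cstr-l1-smth-ring"
variant_label <- function(config) {
  nm <- c(l1 = "l1", l0 = "l0", hl1 = "Hl1", hl0 = "Hl0", l2 = "l2")[config$norm]
  lab <- if (config$norm == "l2") {
    if (config$beta_prime > 0) "l2-smth" else "l2"
  } else {
    paste0(nm, if (config$beta_prime > 0) "-smth", "-ring")
  }
  if (config$constrained) paste0("cstr-", lab) else lab
}

resolve_alpha <- function(config, geometry) {
  if (!is.null(config$alpha)) return(config$alpha)
  nA2 <- operator_norm_sq(geometry)
  if (config$norm == "l2") 1.9 / nA2 else 1.9 / (config$rho * nA2)
}

#' Gradient-descent image update (ADMM step 1)
#'
#' Runs `L` fixed-step gradient-descent iterations on the quadratic image
#' subproblem `D(x) = (rho / 2) * ||c - A x||^2` with
#' `c = lambda + b + u`, using the gradient `-rho * t(A) (c - A x)`; when
#' smoothing is configured each step additionally moves along
#' `-beta_prime * grad H(x)`. Warm-starts from `state$image` (the previous
#' outer iterate). For the l2 baseline the target is simply `b` and
#' `rho = 1` implicitly.
#'
#' @param state solver state: a list with elements `image` (n x n matrix),
#'   `lambda` and `multiplier` (bins x angles matrices).
#' @param sinogram measured sinogram (bins x angles matrix).
#' @param geometry a [ct_geometry()].
#' @param config a [solver_config()].
#' @return The updated image matrix.
#' @export
gd_image_update <- function(state, sinogram, geometry, config) {
  A <- system_matrix(geometry)
  alpha <- resolve_alpha(config, geometry)
  x <- as.vector(state$image)
  n <- geometry$n_pixels
  if (config$norm == "l2") {
    cvec <- as.vector(sinogram)
    rho <- 1
  } else {
    cvec <- as.vector(state$lambda) + as.vector(sinogram) +
      as.vector(state$multiplier)
    rho <- config$rho
  }
  for (l in seq_len(config$L)) {
    grad <- -rho * as.vector(crossprod(A, cvec - A %*% x))
    x <- x - alpha * grad
    if (config$beta_prime > 0)
      x <- x - config$beta_prime *
        as.vector(smoothing_gradient(matrix(x, n, n), config$eta,
                                     config$weights))
    if (!all(is.finite(x)))
      stop("image update diverged (non-finite values); ",
           "the step size alpha is the likely cause")
  }
  matrix(x, n, n)
}

#' Imperfect-component update (ADMM step 2)
#'
#' Applies the proximity operator of the configured sparsity norm with
#' weight `mu = 1 / rho` to `d = A x - b - u`. In the angular-constrained
#' variant `d` is first averaged over angles per detector bin, the prox is
#' applied to the length-`R` average, and the result is replicated across
#' all angles.
#'
#' @inheritParams gd_image_update
#' @return The updated `lambda` matrix (bins x angles).
#' @export
lambda_update <- function(state, sinogram, geometry, config) {
  if (config$norm == "l2")
    return(matrix(0, geometry$n_bins, geometry$n_angles))
  A <- system_matrix(geometry)
  Ax <- as.vector(A %*% as.vector(state$image))
  d <- Ax - as.vector(sinogram) - as.vector(state$multiplier)
  mu <- 1 / config$rho
  if (config$constrained) {
    dbar <- rowMeans(matrix(d, geometry$n_bins, geometry$n_angles))
    lam_bin <- prox_norm(dbar, mu, config$norm, config$delta)
    matrix(lam_bin, geometry$n_bins, geometry$n_angles)
  } else {
    matrix(prox_norm(d, mu, config$norm, config$delta),
           geometry$n_bins, geometry$n_angles)
  }
}

#' Multiplier update (ADMM step 3)
#'
#' Dual ascent on the linear constraint:
#' `u <- u + (lambda - A x + b)`, elementwise over the sinogram grid.
#'
#' @inheritParams gd_image_update
#' @return The updated multiplier matrix (bins x angles).
#' @export
multiplier_update <- function(state, sinogram, geometry, config) {
  A <- system_matrix(geometry)
  Ax <- matrix(as.vector(A %*% as.vector(state$image)),
               geometry$n_bins, geometry$n_angles)
  state$multiplier + (state$lambda - Ax + sinogram)
}

#' Ring-artifact-eliminating reconstruction
#'
#' Jointly estimates the image `x` and the sparse imperfect error component
#' `lambda` of the sinogram from the model `A x = b + lambda` by ADMM on
#' `min S(lambda) (+ beta H(x))  s.t.  A x - b = lambda`, where `S` is one
#' of four sparsity-induced norms and `H` an optional edge-preserving
#' Huber-MRF smoothing penalty. Each outer iteration runs `L` fixed-step
#' gradient-descent updates of the image, a closed-form proximity update of
#' `lambda` (soft/hard/Huber thresholding of `A x - b - u`), and a dual
#' ascent step on the multiplier `u`. With `norm = "l2"` a plain
#' least-squares gradient-descent baseline is run instead (no sparse
#' component; `lambda` stays zero).
#'
#' The recovered `lambda` estimates the per-(bin, angle) sinogram offset
#' responsible for the ring artifacts; bins with large `|lambda|` are the
#' miscalibrated detector elements. Deterministic given identical inputs
#' and configuration.
#'
#' @param sinogram measured sinogram, a `n_bins x n_angles` matrix of
#'   log-attenuation values.
#' @param geometry a [ct_geometry()] matching the sinogram.
#' @param ... configuration values passed to [solver_config()]
#'   (`norm`, `rho`, `K`, `constrained`, `beta_prime`, ...).
#' @param config alternatively, a ready [solver_config()]; `...` must then
#'   be empty.
#' @param reference optional ground-truth image; when supplied, per-
#'   iteration RRMSE and SSIM against it are tracked in the history.
#' @param verbose print a progress line every 100 outer iterations.
#' @return An object of class `ring_recon` with components
#'   \describe{
#'     \item{image}{the reconstructed `n x n` image.}
#'     \item{lambda}{estimated imperfect component (bins x angles); under
#'       `constrained = TRUE` its rows are constant and `lambda_bin` holds
#'       the per-bin profile.}
#'     \item{multiplier}{final scaled dual variable.}
#'     \item{history}{data frame with one row per outer iteration: the
#'       data-fit term `0.5 * ||A x - b - lambda||^2`, the norm value
#'       `S(lambda)`, the smoothing value `H(x)` (if enabled), the primal
#'       residual `||lambda - A x + b||_2`, and RRMSE/SSIM when a reference
#'       is given.}
#'     \item{config, geometry, call}{inputs for reproducibility.}
#'   }
#' @examples
#' g <- ct_geometry(32, 47, 40)
#' ph <- make_phantom(32, "disk")
#' b <- forward_project(ph, g)
#' fit <- ring_recon(b, g, norm = "l1", rho = 1, K = 20)
#' fit
#' @export
ring_recon <- function(sinogram, geometry, ..., config = NULL,
                       reference = NULL, verbose = FALSE) {
  check_sinogram(sinogram, geometry)
  if (is.null(config)) config <- solver_config(...)
  else if (length(list(...)))
    stop("give either `config` or individual settings, not both")
  stopifnot(is(config, "solver_config"))
  if (!is.null(reference)) check_image(reference, geometry)

  R <- geometry$n_bins; Th <- geometry$n_angles; n <- geometry$n_pixels
  state <- list(
    image = if (!is.null(config$init_image)) config$init_image
            else if (config$init == "fbp") fbp_reconstruct(sinogram, geometry)
            else matrix(0, n, n),
    lambda = if (!is.null(config$init_lambda)) config$init_lambda
             else matrix(0, R, Th),
    multiplier = if (!is.null(config$init_multiplier)) config$init_multiplier
                 else matrix(0, R, Th))
  check_image(state$image, geometry)
  A <- system_matrix(geometry)
  bnorm <- sqrt(sum(sinogram^2))
  track_ref <- !is.null(reference)
  K <- config$K
  hist <- data.frame(iter = seq_len(K), datafit = NA_real_,
                     s_lambda = NA_real_, h_x = NA_real_,
                     residual = NA_real_)
  if (track_ref) hist$rrmse <- hist$ssim <- NA_real_
  kstop <- K
  for (k in seq_len(K)) {
    state$image <- gd_image_update(state, sinogram, geometry, config)
    Ax <- matrix(as.vector(A %*% as.vector(state$image)), R, Th)
    # lambda and multiplier updates, reusing the projection of the new image
    # (identical to lambda_update() / multiplier_update())
    if (config$norm != "l2") {
      d <- Ax - sinogram - state$multiplier
      mu <- 1 / config$rho
      state$lambda <- if (config$constrained)
        matrix(prox_norm(rowMeans(d), mu, config$norm, config$delta), R, Th)
      else matrix(prox_norm(d, mu, config$norm, config$delta), R, Th)
      state$multiplier <- state$multiplier + (state$lambda - Ax + sinogram)
    }
    if (!all(is.finite(state$lambda)) || !all(is.finite(state$multiplier)))
      stop("solver state became non-finite at outer iteration ", k)
    resid <- state$lambda - Ax + sinogram
    hist$datafit[k] <- 0.5 * sum((Ax - sinogram - state$lambda)^2)
    hist$s_lambda[k] <- norm_value(state$lambda, config$norm, config$delta)
    hist$h_x[k] <- if (config$beta_prime > 0)
      smoothing_value(state$image, config$eta, config$weights) else NA_real_
    hist$residual[k] <- sqrt(sum(resid^2))
    if (track_ref) {
      hist$rrmse[k] <- rrmse(state$image, reference)
      hist$ssim[k] <- ssim_global(state$image, reference)
    }
    if (verbose && k %% 100 == 0)
      message(sprintf("iter %5d  residual %.3e  S(lambda) %.4g",
                      k, hist$residual[k], hist$s_lambda[k]))
    if (!is.null(config$tol) && bnorm > 0 &&
        hist$residual[k] / bnorm < config$tol) {
      kstop <- k
      break
    }
  }
  hist <- hist[seq_len(kstop), , drop = FALSE]
  out <- list(image = state$image,
              lambda = state$lambda,
              lambda_bin = if (config$constrained) state$lambda[, 1]
                           else NULL,
              multiplier = state$multiplier,
              history = hist,
              iterations = kstop,
              config = config,
              geometry = geometry,
              sinogram = sinogram,
              call = match.call())
  class(out) <- "ring_recon"
  out
}
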