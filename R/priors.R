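norm_kinds <- c("l1", "l0", "hl1", "hl0", "l2")

check_norm <- function(norm, delta) {
  norm <- match.arg(norm, norm_kinds)
  if (norm %in% c("hl1", "hl0") && (!is.numeric(delta) || delta <= 0))
    stop("delta must be > 0 for Huber norms")
  norm
}

#' Sparsity-induced norm value
#'
#' Evaluates the penalty `S(v)` placed on the imperfect sinogram error
#' component: the l1 norm, the l0 counting "norm", the Huber-l1 penalty
#' (quadratic `t^2/2` below the transition point `delta`, linear
#' `delta*|t| - delta^2/2` above, so the two branches meet continuously),
#' the Huber-l0 penalty (quadratic below `delta`, constant `delta^2/2`
#' above), or `||v||_2^2 / 2` for the l2 baseline.
#'
#' @param v numeric vector (or matrix, treated elementwise).
#' @param norm one of `"l1"`, `"l0"`, `"hl1"`, `"hl0"`, `"l2"`.
#' @param delta Huber transition point (> 0); ignored for l1/l0/l2.
#' @return The scalar penalty value.
#' @examples
#' norm_value(c(3, -4), "l1")           # 7
#' norm_value(c(0, 2, 0), "l0")         # 1
#' @export
norm_value <- function(v, norm = c("l1", "l0", "hl1", "hl0", "l2"), delta = 1) {
  norm <- check_norm(norm, delta)
  v <- as.numeric(v)
  if (!all(is.finite(v))) stop("v contains non-finite values")
  a <- abs(v)
  switch(norm,
    l1 = sum(a),
    l0 = sum(a > 0),
    hl1 = sum(ifelse(a < delta, a^2 / 2, delta * a - delta^2 / 2)),
    hl0 = sum(ifelse(a < delta, a^2 / 2, delta^2 / 2)),
    l2 = sum(v^2) / 2)
}

#' Proximity operator of the sparsity-induced norms
#'
#' Elementwise closed-form solution of
#' `argmin_x  mu * s(x) + (x - y)^2 / 2` for the penalty `s` selected by
#' `norm`:
#' \describe{
#'   \item{l1}{soft thresholding at `mu`.}
#'   \item{l0}{hard thresholding: keep `y` iff `y^2 / 2 > mu`, else 0 (the
#'     tie `y^2 / 2 == mu` has two global minimisers; the sparser one, 0, is
#'     returned).}
#'   \item{hl1}{`y / (mu + 1)` in the band `|y| <= (mu + 1) * delta`,
#'     shrink by `mu * delta` outside.}
#'   \item{hl0}{`y / (mu + 1)` in the band `|y| <= delta * sqrt(mu + 1)`,
#'     identity outside. The band edge is where the quadratic-branch
#'     objective `mu * y^2 / (2 * (mu + 1))` meets the keep-`y` objective
#'     `mu * delta^2 / 2`, i.e. the exact minimiser of the Huber-l0
#'     objective.}
#'   \item{l2}{`y / (mu + 1)`.}
#' }
#'
#' @param y numeric vector of inputs.
#' @param mu positive prox weight (the solver uses `mu = 1 / rho`).
#' @param norm,delta see [norm_value()].
#' @return Numeric vector of the same length as `y`.
#' @examples
#' prox_norm(c(5, -5, 1), 2, "l1")    # 3 -3 0
#' prox_norm(c(3, 1.5), 2, "l0")      # 3 0
#' @export
prox_norm <- function(y, mu, norm = c("l1", "l0", "hl1", "hl0", "l2"),
                      delta = 1) {
  norm <- check_norm(norm, delta)
  if (!is.numeric(mu) || length(mu) != 1 || mu <= 0)
    stop("mu must be a positive scalar")
  a <- abs(y)
  switch(norm,
    l1 = sign(y) * pmax(a - mu, 0),
    l0 = ifelse(a^2 / 2 > mu, y, 0),
    hl1 = ifelse(a > (mu + 1) * delta, y - sign(y) * mu * delta, y / (mu + 1)),
    hl0 = ifelse(a > delta * sqrt(mu + 1), y, y / (mu + 1)),
    l2 = y / (mu + 1))
}

# 8-neighbour stencil: offsets and weights (inverse Euclidean distance by
# default: 1 for axial, 1/sqrt(2) for diagonal neighbours; "distance" keeps
# the literal reading with diagonals up-weighted by sqrt(2))
neighbor_stencil <- function(weights = c("inverse_distance", "distance")) {
  weights <- match.arg(weights)
  off <- cbind(dx = c(-1, 1, 0, 0, -1, -1, 1, 1),
               dy = c(0, 0, -1, 1, -1, 1, -1, 1))
  d <- sqrt(off[, 1]^2 + off[, 2]^2)
  w <- if (weights == "inverse_distance") 1 / d else d
  list(off = off, w = w)
}

# apply f(diff, w) over all 8 shifted neighbour differences and accumulate;
# neighbour sets are truncated at the image boundary (no padding)
shift_accumulate <- function(image, weights, f) {
  n1 <- nrow(image); n2 <- ncol(image)
  st <- neighbor_stencil(weights)
  acc <- matrix(0, n1, n2)
  for (k in seq_len(nrow(st$off))) {
    dx <- st$off[k, 1]; dy <- st$off[k, 2]
    if (max(1, 1 + dx) > min(n1, n1 + dx) ||
        max(1, 1 + dy) > min(n2, n2 + dy)) next   # no overlap (thin images)
    xi <- max(1, 1 + dx):min(n1, n1 + dx)
    yi <- max(1, 1 + dy):min(n2, n2 + dy)
    diff <- image[xi - dx, yi - dy, drop = FALSE] -
      image[xi, yi, drop = FALSE]
    acc[xi - dx, yi - dy] <- acc[xi - dx, yi - dy] + f(diff, st$w[k])
  }
  acc
}

#' Edge-preserving smoothing penalty (Huber MRF)
#'
#' `H(x) = sum_j sum_{j~ in U_j} w_jj~ * h(x_j - x_j~)` where `U_j` is the
#' 8-neighbourhood of pixel `j` (truncated at image borders), `w` weights
#' neighbours by inverse Euclidean distance, and `h` is quadratic below the
#' edge threshold `eta` and linear (`eta*|t| - eta^2/2`) above it, so large
#' jumps are penalised linearly and edges are preserved. Each unordered
#' neighbour pair contributes twice (once from each pixel's neighbour set).
#'
#' @param image `n1 x n2` numeric matrix.
#' @param eta Huber edge threshold (> 0), in image-intensity units.
#' @param weights `"inverse_distance"` (default) or `"distance"`.
#' @return Scalar penalty value.
#' @export
smoothing_value <- function(image, eta, weights = "inverse_distance") {
  if (!is.numeric(eta) || eta <= 0) stop("eta must be > 0")
  h <- function(diff, w) {
    a <- abs(diff)
    w * ifelse(a < eta, a^2 / 2, eta * a - eta^2 / 2)
  }
  sum(shift_accumulate(image, weights, h))
}

#' Gradient of the smoothing penalty
#'
#' Exact gradient of [smoothing_value()]: per pixel, twice the weighted sum
#' over its 8 neighbours of the difference clipped to `[-eta, eta]` (the
#' factor 2 accounts for each pair appearing in both pixels' neighbour
#' sets, so central finite differences of [smoothing_value()] match this
#' gradient).
#'
#' @inheritParams smoothing_value
#' @return Matrix of the same shape as `image`.
#' @export
smoothing_gradient <- function(image, eta, weights = "inverse_distance") {
  if (!is.numeric(eta) || eta <= 0) stop("eta must be > 0")
  g <- function(diff, w) w * pmin(pmax(diff, -eta), eta)
  2 * shift_accumulate(image, weights, g)
}
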