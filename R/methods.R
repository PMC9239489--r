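#' @export
print.ring_recon <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Ring-elimination reconstruction (%s)\n", variant_label(cfg)))
  cat(sprintf("  image: %d x %d, sinogram: %d bins x %d angles\n",
              x$geometry$n_pixels, x$geometry$n_pixels,
              x$geometry$n_bins, x$geometry$n_angles))
  cat(sprintf("  outer iterations: %d (L = %d inner GD steps each)\n",
              x$iterations, cfg$L))
  h <- x$history[x$iterations, ]
  bnorm <- sqrt(sum(x$sinogram^2))
  cat(sprintf("  final primal residual: %.3e (relative %.3e)\n",
              h$residual, h$residual / bnorm))
  if (cfg$norm != "l2")
    cat(sprintf("  S(lambda) = %.4g, nonzero bins: %d of %d\n",
                h$s_lambda, sum(rowSums(abs(x$lambda)) > 0),
                x$geometry$n_bins))
  if (!is.null(h$rrmse) && is.finite(h$rrmse))
    cat(sprintf("  vs reference: RRMSE %.4f, SSIM %.4f\n", h$rrmse, h$ssim))
  invisible(x)
}

#' @export
summary.ring_recon <- function(object, top = 10, ...) {
  prof <- lambda_profile(object)
  ord <- order(abs(prof), decreasing = TRUE)
  top <- min(top, sum(abs(prof) > 0), length(prof))
  structure(list(fit = object,
                 top_bins = if (top > 0)
                   data.frame(bin = ord[seq_len(top)],
                              lambda = prof[ord[seq_len(top)]])
                 else data.frame(bin = integer(), lambda = numeric())),
            class = "summary.ring_recon")
}

#' @export
print.summary.ring_recon <- function(x, ...) {
  print(x$fit)
  if (nrow(x$top_bins)) {
    cat("  largest |lambda| detector bins (angle-mean):\n")
    print(x$top_bins, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Per-bin profile of the estimated imperfect component
#'
#' The angle-mean of the estimated `lambda` for each detector bin (exactly
#' the per-bin value under the angular-constrained variant). Bins with
#' large `|lambda|` are the detected miscalibrated detector elements.
#'
#' @param object a [ring_recon()] fit.
#' @return Numeric vector of length `n_bins`.
#' @export
lambda_profile <- function(object) {
  stopifnot(is(object, "ring_recon"))
  if (!is.null(object$lambda_bin)) object$lambda_bin
  else rowMeans(object$lambda)
}

#' @export
#' @describeIn ring_recon `coef` returns the estimated imperfect component:
#'   the full bins x angles matrix (`type = "matrix"`) or the per-bin
#'   angle-mean profile (`type = "bin"`).
#' @param object,x a `ring_recon` fit.
#' @param type what to extract.
coef.ring_recon <- function(object, type = c("matrix", "bin"), ...) {
  type <- match.arg(type)
  if (type == "bin") lambda_profile(object) else object$lambda
}

#' @export
fitted.ring_recon <- function(object, ...) object$image

#' @export
#' @describeIn ring_recon `residuals` returns the primal residual
#'   `lambda - A x + b` (bins x angles); at convergence it vanishes.
residuals.ring_recon <- function(object, ...) {
  Ax <- forward_project(object$image, object$geometry)
  object$lambda - Ax + object$sinogram
}

#' @export
#' @describeIn ring_recon `predict` returns the model sinogram of the
#'   reconstruction: the ideal projections `A x` (`what = "ideal"`) or the
#'   corrupted model `A x - lambda` comparable to the measured data
#'   (`what = "measured"`).
#' @param what which model sinogram to return.
predict.ring_recon <- function(object, what = c("ideal", "measured"), ...) {
  what <- match.arg(what)
  Ax <- forward_project(object$image, object$geometry)
  if (what == "ideal") Ax else Ax - object$lambda
}

#' @export
#' @describeIn ring_recon `plot` shows the reconstruction, the per-bin
#'   `lambda` profile, and the convergence history (relative primal
#'   residual, plus RRMSE when a reference was tracked).
plot.ring_recon <- function(x, ...) {
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  image(x$image, col = gray.colors(256), asp = 1, axes = FALSE,
        main = sprintf("reconstruction (%s)", variant_label(x$config)))
  prof <- lambda_profile(x)
  plot(seq_along(prof), prof, type = "h", xlab = "detector bin",
       ylab = "lambda (angle mean)", main = "imperfect component")
  bnorm <- sqrt(sum(x$sinogram^2))
  plot(x$history$iter, x$history$residual / bnorm, type = "l", log = "y",
       xlab = "outer iteration", ylab = "relative primal residual",
       main = "convergence")
  if (!is.null(x$history$rrmse) && any(is.finite(x$history$rrmse))) {
    plot(x$history$iter, x$history$rrmse, type = "l",
         xlab = "outer iteration", ylab = "RRMSE", main = "error vs reference")
  } else {
    plot(x$history$iter, x$history$s_lambda, type = "l",
         xlab = "outer iteration", ylab = "S(lambda)",
         main = "sparsity penalty")
  }
  invisible(x)
}
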