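# small shared fixture: disk phantom in a modest geometry
solver_fix <- local({
  env <- new.env()
  function() {
    if (is.null(env$fx)) {
      g <- ct_geometry(48, 69, 60, angular_range = 360)
      ph <- make_phantom(48, "disk")
      env$fx <- list(g = g, ph = ph, b = forward_project(ph, g))
    }
    env$fx
  }
})

test_that("gradient step is stationary at the solution and explicit from zero", {
  fx <- solver_fix()
  cfg <- solver_config(norm = "l1", rho = 1, alpha = 1e-5, K = 1, L = 1)
  # lambda = u = 0, b = A x*, start at x*: gradient vanishes
  st <- list(image = fx$ph,
             lambda = matrix(0, 69, 60), multiplier = matrix(0, 69, 60))
  expect_equal(gd_image_update(st, fx$b, fx$g, cfg), fx$ph, tolerance = 1e-12)
  # one step from zero equals alpha * rho * t(A) (lambda + b + u)
  st0 <- list(image = matrix(0, 48, 48),
              lambda = matrix(0, 69, 60), multiplier = matrix(0, 69, 60))
  expect_equal(gd_image_update(st0, fx$b, fx$g, cfg),
               1e-5 * 1 * back_project(fx$b, fx$g), tolerance = 1e-12)
})

test_that("gradient descent decreases the quadratic objective monotonically", {
  g <- ct_geometry(32, 47, 40, angular_range = 360)
  set.seed(5)
  b <- matrix(rnorm(47 * 40), 47, 40)
  D <- function(x) 0.5 * sum((b - forward_project(x, g))^2)
  cfg <- solver_config(norm = "l2", K = 1, L = 1)
  st <- list(image = matrix(0, 32, 32), lambda = matrix(0, 47, 40),
             multiplier = matrix(0, 47, 40))
  vals <- D(st$image)
  for (k in 1:10) {
    st$image <- gd_image_update(st, b, g, cfg)
    vals <- c(vals, D(st$image))
  }
  expect_true(all(diff(vals) <= 0))
})

test_that("lambda update applies the prox of d, with angular averaging when constrained", {
  fx <- solver_fix()
  R <- 69; Th <- 60
  zero <- matrix(0, R, Th)
  # x = 0, u = 0, b = 0 -> d = 0 -> lambda = 0 for every norm
  st <- list(image = matrix(0, 48, 48), lambda = zero, multiplier = zero)
  for (nrm in c("l1", "l0", "hl1", "hl0"))
    expect_equal(lambda_update(st, zero, fx$g,
                               solver_config(norm = nrm, rho = 2, delta = 0.5)),
                 zero)
  # d has a single entry 5 (b = -5 there): l1 prox with mu = 2 gives 3
  b <- zero; b[10, 3] <- -5
  lam <- lambda_update(st, b, fx$g, solver_config(norm = "l1", rho = 0.5))
  expect_equal(lam[10, 3], 3)
  expect_equal(sum(lam != 0), 1)
  # angular-constrained: alternating +4/-4 across angles cancels
  b2 <- zero; b2[10, ] <- c(-4, 4)
  lam2 <- lambda_update(st, b2, fx$g,
                        solver_config(norm = "l1", rho = 0.5, constrained = TRUE))
  expect_equal(lam2, zero)
})

test_that("multiplier update accumulates the constraint violation", {
  fx <- solver_fix()
  zero <- matrix(0, 69, 60)
  st <- list(image = matrix(0, 48, 48), lambda = zero, multiplier = zero)
  # u = 0, lambda = 0, x = 0 -> u = b
  expect_equal(multiplier_update(st, fx$b, fx$g, solver_config()), fx$b)
  # satisfied constraint leaves u unchanged
  st2 <- list(image = fx$ph, lambda = -fx$b + forward_project(fx$ph, fx$g),
              multiplier = fx$b * 0.3)
  expect_equal(multiplier_update(st2, fx$b, fx$g, solver_config()),
               fx$b * 0.3, tolerance = 1e-12)
})

test_that("one outer iteration from zero equals the hand-computed composition", {
  fx <- solver_fix()
  alpha <- 1e-5; rho <- 0.5
  cfg <- solver_config(norm = "l1", rho = rho, alpha = alpha, K = 1, L = 1)
  fit <- ring_recon(fx$b, fx$g, config = cfg)
  x1 <- alpha * rho * back_project(fx$b, fx$g)
  d1 <- forward_project(x1, fx$g) - fx$b
  lam1 <- matrix(prox_norm(d1, 1 / rho, "l1"), 69, 60)
  u1 <- lam1 - forward_project(x1, fx$g) + fx$b
  expect_equal(fit$image, x1, tolerance = 1e-12)
  expect_equal(fit$lambda, lam1, tolerance = 1e-12)
  expect_equal(fit$multiplier, u1, tolerance = 1e-12)
})

test_that("the four variants differ only through the prox operator", {
  fx <- solver_fix()
  fits <- lapply(c("l1", "l0", "hl1", "hl0"), function(nrm)
    ring_recon(fx$b, fx$g, norm = nrm, rho = 2, delta = 0.3, K = 1, L = 2))
  # identical image update (the x-step never sees the norm on iteration 1)
  for (f in fits[-1]) expect_equal(f$image, fits[[1]]$image, tolerance = 1e-14)
  # each lambda is the corresponding prox of the SAME d
  d <- forward_project(fits[[1]]$image, fx$g) - fx$b
  for (i in seq_along(fits))
    expect_equal(fits[[i]]$lambda,
                 matrix(prox_norm(d, 1 / 2, c("l1", "l0", "hl1", "hl0")[i], 0.3),
                        69, 60),
                 tolerance = 1e-14)
})

test_that("clean noise-free data yields a near-zero imperfect component", {
  fx <- solver_fix()
  fit <- ring_recon(fx$b, fx$g, norm = "l1", rho = 0.25, K = 400, L = 2,
                    reference = fx$ph)
  expect_lt(max(abs(fit$lambda)), 1e-6)
  l2fit <- ring_recon(fx$b, fx$g, norm = "l2", K = 300, L = 2,
                      reference = fx$ph)
  # comparable accuracy to the l2 reconstruction on clean data
  expect_lt(tail(fit$history$rrmse, 1), tail(l2fit$history$rrmse, 1) + 0.02)
  # l2 baseline never produces a sparse component and decreases RRMSE
  expect_equal(l2fit$lambda, matrix(0, 69, 60))
  expect_true(all(diff(l2fit$history$rrmse) <= 1e-12))
})

test_that("angular-constrained lambda is exactly constant across angles", {
  fx <- solver_fix()
  model <- ring_error_model(69, n_bad = 3, seed = 4)
  cor <- corrupt_sinogram(fx$b, model)
  fit <- ring_recon(cor$sinogram, fx$g, norm = "l1", rho = 4, K = 50,
                    constrained = TRUE)
  expect_true(all(fit$lambda == fit$lambda[, 1]))
  expect_equal(fit$lambda_bin, fit$lambda[, 1])
})

test_that("solver runs are deterministic and support early stopping", {
  fx <- solver_fix()
  f1 <- ring_recon(fx$b, fx$g, norm = "l1", rho = 1, K = 20)
  f2 <- ring_recon(fx$b, fx$g, norm = "l1", rho = 1, K = 20)
  expect_identical(f1$image, f2$image)
  expect_identical(f1$lambda, f2$lambda)
  expect_equal(nrow(f1$history), 20)
  ft <- ring_recon(fx$b, fx$g, norm = "l1", rho = 1, K = 500, tol = 1e-2)
  expect_lt(ft$iterations, 500)
  expect_lt(tail(ft$history$residual, 1) / sqrt(sum(fx$b^2)), 1e-2)
})

test_that("a divergent step size raises a diagnostic error naming alpha", {
  fx <- solver_fix()
  # (the sparse-norm variants absorb the blow-up into lambda, so the pure
  # least-squares baseline is the cleanest divergence trigger)
  expect_error(ring_recon(fx$b, fx$g, norm = "l2", alpha = 10, K = 60),
               "alpha")
})

test_that("l2 baseline keeps rings that the sparse norms remove", {
  fx <- solver_fix()
  model <- ring_error_model(69, n_bad = 3, seed = 5)  # distinct ring radii
  cor <- corrupt_sinogram(fx$b, model)
  l2fit <- ring_recon(cor$sinogram, fx$g, norm = "l2", K = 300, L = 2)
  l1fit <- ring_recon(cor$sinogram, fx$g, norm = "l1", rho = 4, K = 400, L = 2,
                      constrained = TRUE)
  radii <- ring_radii(fx$g, model$bad_bins)
  e2 <- radial_max_error(l2fit$image, fx$ph, radii)
  e1 <- radial_max_error(l1fit$image, fx$ph, radii)
  expect_gt(max(e2), 3 * attr(e2, "background"))  # rings persist under l2
  expect_lt(mean(e1), mean(e2))                   # sparse norm suppresses them
})

test_that("fitted model methods expose the estimate consistently", {
  fx <- solver_fix()
  model <- ring_error_model(69, n_bad = 3, seed = 4)
  cor <- corrupt_sinogram(fx$b, model)
  fit <- ring_recon(cor$sinogram, fx$g, norm = "l1", rho = 4, K = 60,
                    constrained = TRUE, reference = fx$ph)
  expect_identical(fitted(fit), fit$image)
  expect_identical(coef(fit), fit$lambda)
  expect_equal(coef(fit, type = "bin"), fit$lambda[, 1])
  expect_equal(residuals(fit),
               fit$lambda - forward_project(fit$image, fx$g) + cor$sinogram)
  expect_equal(predict(fit, what = "measured"),
               predict(fit, what = "ideal") - fit$lambda)
  expect_output(print(fit), "cstr-l1-ring")
  expect_output(print(summary(fit)), "largest")
  expect_equal(nrow(fit$history), 60)
  expect_true(all(c("rrmse", "ssim") %in% names(fit$history)))
  pf <- tempfile(fileext = ".pdf")
  grDevices::pdf(pf)
  expect_silent(plot(fit))
  grDevices::dev.off()
  expect_true(file.exists(pf))
  unlink(pf)
})
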