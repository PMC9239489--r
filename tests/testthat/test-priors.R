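test_that("norm values match direct piecewise evaluation", {
  expect_equal(norm_value(c(0, 0, 0), "l1"), 0)
  expect_equal(norm_value(c(0, 0, 0), "hl1", delta = 0.5), 0)
  expect_equal(norm_value(c(3, -4), "l1"), 7)
  expect_equal(norm_value(c(0, 2, -1, 0), "l0"), 2)
  expect_equal(norm_value(c(3, -4), "l2"), 12.5)

  # Huber-l1 at delta = 0.1: 0.05 is in the quadratic branch, 2.0 in the
  # linear branch delta*|t| - delta^2/2 (continuous at |t| = delta)
  expect_equal(norm_value(c(0.05, 2.0), "hl1", delta = 0.1),
               0.05^2 / 2 + (0.1 * 2.0 - 0.1^2 / 2))
  expect_equal(norm_value(c(0.05, 2.0), "hl1", delta = 0.1),
               sum(ref_penalty(c(0.05, 2.0), "hl1", 0.1)))
  # continuity of both Huber branches at the transition point
  eps <- 1e-9
  for (nrm in c("hl1", "hl0")) {
    expect_equal(norm_value(0.1 - eps, nrm, delta = 0.1),
                 norm_value(0.1 + eps, nrm, delta = 0.1),
                 tolerance = 1e-6)
  }
  expect_error(norm_value(1, "hl1", delta = -1), "delta")
})

test_that("prox closed forms match known values", {
  # soft thresholding
  expect_equal(prox_norm(5, 2, "l1"), 3)
  expect_equal(prox_norm(-5, 2, "l1"), -3)
  expect_equal(prox_norm(1, 2, "l1"), 0)
  # hard thresholding, including the tie broken toward 0
  expect_equal(prox_norm(3, 2, "l0"), 3)       # 9/2 > 2
  expect_equal(prox_norm(1.5, 2, "l0"), 0)     # 1.125 <= 2
  expect_equal(prox_norm(2, 2, "l0"), 0)       # tie: y^2/2 == mu
  # Huber-l1 inside the band
  expect_equal(prox_norm(0.5, 1, "hl1", delta = 1), 0.25)
  expect_error(prox_norm(1, -1, "l1"), "mu")
})

test_that("closed-form prox attains the brute-force objective on a grid", {
  mus <- c(0.5, 2)
  deltas <- c(0.1, 1)
  ys <- seq(-5, 5, length.out = 41)
  for (mu in mus) {
    for (y in ys) {
      for (norm in c("l1", "l0")) {
        p <- prox_norm(y, mu, norm)
        gbest <- ref_prox_grid(y, mu, norm, step = 1e-3)
        expect_lte(ref_prox_objective(p, y, mu, norm),
                   ref_prox_objective(gbest, y, mu, norm) + 1e-9)
        if (norm == "l1") expect_lt(abs(p - gbest), 2e-3)
      }
      for (delta in deltas) {
        for (norm in c("hl1", "hl0")) {
          p <- prox_norm(y, mu, norm, delta)
          gbest <- ref_prox_grid(y, mu, norm, delta, step = 1e-3)
          expect_lte(ref_prox_objective(p, y, mu, norm, delta),
                     ref_prox_objective(gbest, y, mu, norm, delta) + 1e-9)
          if (norm == "hl1") expect_lt(abs(p - gbest), 2e-3)
        }
      }
    }
  }
})

test_that("prox operators are odd, fix zero, and convex ones are nonexpansive", {
  set.seed(3)
  ys <- runif(200, -10, 10)
  for (norm in c("l1", "l0", "hl1", "hl0")) {
    expect_equal(prox_norm(0, 0.7, norm, delta = 0.4), 0)
    expect_equal(prox_norm(-ys, 0.7, norm, delta = 0.4),
                 -prox_norm(ys, 0.7, norm, delta = 0.4))
  }
  for (norm in c("l1", "hl1")) {
    p <- prox_norm(ys, 1.3, norm, delta = 0.4)
    i <- seq(1, 199, by = 2); j <- i + 1
    expect_true(all(abs(p[i] - p[j]) <= abs(ys[i] - ys[j]) + 1e-12))
  }
  # delta -> Inf: both Huber proxes approach the pure quadratic limit
  for (norm in c("hl1", "hl0"))
    expect_equal(prox_norm(ys, 1.3, norm, delta = 1e9), ys / 2.3,
                 tolerance = 1e-10)
})

test_that("smoothing value follows the pairwise Huber sum", {
  expect_equal(smoothing_value(matrix(5, 7, 7), eta = 0.1), 0)
  # two horizontally adjacent pixels, difference t: the pair is counted from
  # both sides with axial weight 1
  t_small <- 0.04; eta <- 0.1
  m <- matrix(c(1, 1 + t_small), 2, 1)
  expect_equal(smoothing_value(m, eta), 2 * t_small^2 / 2)
  t_big <- 0.5
  m2 <- matrix(c(1, 1 + t_big), 2, 1)
  expect_equal(smoothing_value(m2, eta), 2 * (eta * t_big - eta^2 / 2))
  # diagonal neighbours carry weight 1/sqrt(2) by default, sqrt(2) literal
  d <- matrix(c(0, 0, 0, t_small), 2, 2)
  v_inv <- smoothing_value(d, eta)
  v_lit <- smoothing_value(d, eta, weights = "distance")
  expect_equal(v_inv, 2 * (1 / sqrt(2)) * t_small^2 / 2 + 2 * 2 * t_small^2 / 2)
  expect_equal(v_lit, 2 * sqrt(2) * t_small^2 / 2 + 2 * 2 * t_small^2 / 2)
  expect_error(smoothing_value(d, eta = 0), "eta")
})

test_that("smoothing gradient matches finite differences and is odd", {
  set.seed(11)
  # values on a 0.1 grid keep all pairwise differences away from the
  # |diff| = eta kink where the Huber penalty is not differentiable
  img <- matrix(round(rnorm(64), 1), 8, 8)
  eta <- 0.35
  g <- smoothing_gradient(img, eta)
  h <- 1e-6
  for (idx in c(1, 9, 28, 37, 64)) {
    up <- img; up[idx] <- up[idx] + h
    dn <- img; dn[idx] <- dn[idx] - h
    fd <- (smoothing_value(up, eta) - smoothing_value(dn, eta)) / (2 * h)
    expect_equal(g[idx], fd, tolerance = 1e-5)
  }
  expect_equal(smoothing_gradient(-img, eta), -g)
  expect_equal(smoothing_gradient(matrix(2, 5, 5), eta), matrix(0, 5, 5))
})
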