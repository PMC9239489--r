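# Independent reference implementations used as oracles. These deliberately
# use plain scalar loops / direct formula transcriptions so they share no
# code with the package internals they check.

# elementwise sparsity penalties (quadratic-continuous Huber branches)
ref_penalty <- function(x, norm, delta = 1) {
  a <- abs(x)
  switch(norm,
    l1 = a,
    l0 = as.numeric(a > 0),
    hl1 = ifelse(a < delta, a^2 / 2, delta * a - delta^2 / 2),
    hl0 = ifelse(a < delta, a^2 / 2, delta^2 / 2),
    l2 = x^2 / 2)
}

# dense-grid brute-force prox: argmin_x mu*s(x) + (x - y)^2 / 2
ref_prox_grid <- function(y, mu, norm, delta = 1, step = 1e-4) {
  lim <- max(6, abs(y) + 1)
  xs <- seq(-lim, lim, by = step)
  obj <- mu * ref_penalty(xs, norm, delta) + 0.5 * (xs - y)^2
  xs[which.min(obj)]
}

ref_prox_objective <- function(x, y, mu, norm, delta = 1) {
  mu * ref_penalty(x, norm, delta) + 0.5 * (x - y)^2
}

# scalar-loop Joseph system matrix (dense); independent of the vectorised
# construction in the package
ref_system_matrix <- function(g) {
  n <- g$n_pixels; R <- g$n_bins; Th <- g$n_angles; ds <- g$detector_spacing
  A <- matrix(0, R * Th, n * n)
  ctr <- (n + 1) / 2
  for (t in seq_len(Th)) {
    ca <- cos(g$angles[t]); sa <- sin(g$angles[t])
    for (r in seq_len(R)) {
      s <- (r - (R + 1) / 2) * ds
      row <- (t - 1) * R + r
      if (abs(ca) >= abs(sa)) {
        w <- 1 / abs(ca)
        for (j in seq_len(n)) {
          x <- (s - (j - ctr) * sa) / ca + ctr
          i0 <- floor(x); fr <- x - i0
          if (i0 >= 1 && i0 <= n)
            A[row, i0 + (j - 1) * n] <- A[row, i0 + (j - 1) * n] + (1 - fr) * w
          if (i0 + 1 >= 1 && i0 + 1 <= n)
            A[row, i0 + 1 + (j - 1) * n] <- A[row, i0 + 1 + (j - 1) * n] + fr * w
        }
      } else {
        w <- 1 / abs(sa)
        for (i in seq_len(n)) {
          y <- (s - (i - ctr) * ca) / sa + ctr
          j0 <- floor(y); fr <- y - j0
          if (j0 >= 1 && j0 <= n)
            A[row, i + (j0 - 1) * n] <- A[row, i + (j0 - 1) * n] + (1 - fr) * w
          if (j0 + 1 >= 1 && j0 + 1 <= n)
            A[row, i + j0 * n] <- A[row, i + j0 * n] + fr * w
        }
      }
    }
  }
  A
}

# elementwise-loop RRMSE and moment-by-moment SSIM
ref_rrmse <- function(x, z) {
  se <- 0; zz <- 0
  for (i in seq_along(x)) {
    se <- se + (x[i] - z[i])^2
    zz <- zz + z[i]^2
  }
  sqrt(se) / sqrt(zz)
}

ref_ssim <- function(x, z, k1 = 0.01, k2 = 0.03) {
  x <- as.vector(x); z <- as.vector(z)
  N <- length(x)
  mx <- sum(x) / N; mz <- sum(z) / N
  vx <- sum((x - mx)^2) / N; vz <- sum((z - mz)^2) / N
  cxz <- sum((x - mx) * (z - mz)) / N
  s <- max(z) - min(z)
  c1 <- (k1 * s)^2; c2 <- (k2 * s)^2
  ((2 * mx * mz + c1) * (2 * cxz + c2)) /
    ((mx^2 + mz^2 + c1) * (vx + vz + c2))
}
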