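# ringrec — sparsity-based ring artifact elimination for parallel-beam CT

Ring artifacts are concentric bright/dark circles in reconstructed CT
images caused by miscalibrated detector bins; in the sinogram they are
vertical stripes. `ringrec` removes them *during* reconstruction rather
than by pre- or post-filtering: the projection data is modelled as an
ideal part plus a sparse "imperfect" error component λ,

    A x = b + λ,

where `A` is the parallel-beam system matrix, `b` the measured
log-attenuation sinogram and λ is nonzero only at bad detector bins. The
image and the error are estimated jointly,

    min_{x, λ}  S(λ) ( + β H(x) )   s.t.   A x − b = λ,

with `S` one of four sparsity-induced norms — ℓ1, ℓ0, Huber-ℓ1,
Huber-ℓ0 — and `H` an optional edge-preserving Huber-MRF smoothing
penalty. The problem is solved by ADMM: `L` fixed-step gradient-descent
updates of `x` on the augmented-Lagrangian quadratic, a closed-form
proximity update of λ (soft / hard / Huber thresholding of
`d = A x − b − u` with weight `μ = 1/ρ`), and dual ascent on the
multiplier `u`. The four algorithm variants differ *only* in the prox.
An angular-constrained form handles the pure detector-sensitivity case
(λ identical across angles per bin) by applying the prox to the
angle-averaged `d`. A plain ℓ2/gradient-descent baseline and filtered
back-projection (Ram-Lak) are included for comparison, along with a
simulator for detector-error + Poisson-noise studies and RRMSE/SSIM
metrics.

The audience is researchers in tomographic image reconstruction and
biomedical imaging who want a reference implementation of
in-reconstruction ring elimination, a controlled simulator for detector
errors, or the building blocks (matched sparse projector pair, prox
operators, FBP) for their own experiments.

## Worked example

```r
library(ringrec)

# scaled noise-free study case 1: 128x128 chest-like phantom,
# 185 detector bins x 250 angles over 360 deg, 5 bad bins
sc  <- make_study_case(1, n = 128, n_bins = 185, n_angles = 250, seed = 1)
fit <- ring_recon(sc$corrupted, sc$geometry, norm = "l1", rho = 4,
                  K = 500, constrained = TRUE, reference = sc$phantom)
summary(fit, top = 5)
```

```
Ring-elimination reconstruction (cstr-l1-ring)
  image: 128 x 128, sinogram: 185 bins x 250 angles
  outer iterations: 500 (L = 2 inner GD steps each)
  final primal residual: 1.822e+00 (relative 6.256e-04)
  S(lambda) = 1881, nonzero bins: 7 of 185
  vs reference: RRMSE 0.0451, SSIM 0.9986
  largest |lambda| detector bins (angle-mean):
 bin  lambda
 139  2.4664
 172  1.7241
  53  1.2401
  78  1.1174
  24 -0.8483
```

The five largest recovered per-bin offsets are exactly the five injected
bad bins (`sc$model$bad_bins` is 24, 53, 78, 139, 172), with magnitudes
within a few percent of the injected values (`sc$lambda_true`). The
reconstruction error (RRMSE 0.045) is less than half that of filtered
back-projection of the corrupted data:

```r
rrmse(fbp_reconstruct(sc$corrupted, sc$geometry), sc$phantom)
#> [1] 0.09883434
```

Adding the smoothing penalty to the ℓ0 variant removes the remaining
high-frequency error almost entirely:

```r
fit0 <- ring_recon(sc$corrupted, sc$geometry, norm = "l0", rho = 4,
                   K = 500, init = "fbp", beta_prime = 0.02, eta = 0.01,
                   reference = sc$phantom)
rrmse(fit0$image, sc$phantom)
#> [1] 0.00835679
```

`plot(fit)` shows the reconstruction, the per-bin λ profile and the
convergence history. Methods `coef()`, `fitted()`, `residuals()` and
`predict()` expose the estimated error component, the image, the primal
residual `λ − A x + b` and the model sinogram.

A command-line interface is installed as `exec/ringct` with subcommands
`simulate`, `reconstruct`, `evaluate` and `run-all`; all options can
also be given via a flat key-value config file
(see `inst/extdata/paper_case1_small.cfg`).

Parameter scaling rules (ρ, δ, β′, η are tied to the data scale), the
choice of initialisation for the nonconvex norms, and the limits of what
the simulator demonstrates are documented in the methods vignette,
`vignettes/ring-artifact-elimination.Rmd`.

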