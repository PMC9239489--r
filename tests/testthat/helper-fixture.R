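# Scaled noise-free study-case-1 fixture shared by the acceptance tests:
# 128^2 chest-like phantom, 185 bins x 250 angles over 360 degrees, 5
# non-adjacent angle-constant bad detector bins, fixed seed. Solver
# configurations follow the scale-adaptation rules in the methods vignette
# (l1: rho = 4; Huber: mu = 25 with matched delta; nonconvex norms start
# from FBP). Heavy solves are computed lazily and cached for reuse across
# test blocks.
acceptance_fixture <- local({
  env <- new.env()
  function(what = "base") {
    if (is.null(env$base)) {
      sc <- make_study_case(1, n = 128, n_bins = 185, n_angles = 250,
                            seed = 1)
      fbp_corr <- fbp_reconstruct(sc$corrupted, sc$geometry)
      env$base <- list(
        sc = sc,
        bad_bins = sc$model$bad_bins,
        fbp_corr = fbp_corr,
        rrmse_fbp = rrmse(fbp_corr, sc$phantom))
    }
    if (what == "base") return(env$base)
    if (is.null(env[[what]])) {
      sc <- env$base$sc
      run <- function(...) ring_recon(sc$corrupted, sc$geometry, ...,
                                      K = 500, L = 2,
                                      reference = sc$phantom)
      env[[what]] <- switch(what,
        cstr_l1 = run(norm = "l1", rho = 4, constrained = TRUE),
        l1 = run(norm = "l1", rho = 4),
        hl1 = run(norm = "hl1", rho = 0.04, delta = 0.025),
        l2 = run(norm = "l2"),
        l0_smth = run(norm = "l0", rho = 4, init = "fbp",
                      beta_prime = 0.02, eta = 0.01))
    }
    env[[what]]
  }
})
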