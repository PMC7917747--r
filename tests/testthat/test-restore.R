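test_that("fidelity-dominated restoration reproduces the observation", {
  img <- small_star(64L)
  g <- convolvePSF(img, deltaPSF(5L)) # delta kernel, no noise
  res <- restoreImage(g, deltaPSF(5L),
                      regularizationParams(alpha = 1e8),
                      solverConfig(gpbbIterations = 10L, hqsPasses = 4L))
  rel <- sqrt(sum((res$image - g)^2)) / sqrt(sum(g^2))
  expect_lt(rel, 1e-3)
})

test_that("whole-pass energies are non-increasing within each fixed-gamma subproblem", {
  img <- small_star(96L)
  g <- degradeImage(img, degradationSpec(psf = gaussianPSF(9L, 1.2),
                                         noiseVariance = 1e-4, rngSeed = 3L))
  for (mode in c("bi-l0-l2", "l1")) {
    res <- restoreImage(g, gaussianPSF(9L, 1.2),
                        regularizationParams(mode = mode))
    tr <- res$trace
    expect_true(all(is.finite(tr$objective_values)))
    expect_true(all(tr$pass_end <= tr$pass_start + 1e-8))
  }
})

test_that("restored intensities respect the feasible box exactly", {
  img <- small_star(64L)
  g <- degradeImage(img, degradationSpec(psf = gaussianPSF(9L, 1.5),
                                         noiseVariance = 0.01, rngSeed = 4L))
  res <- restoreImage(g, gaussianPSF(9L, 1.5),
                      cfg = solverConfig(boxLow = 0.1, boxHigh = 0.9))
  expect_gte(min(res$image), 0.1)
  expect_lte(max(res$image), 0.9)
})

test_that("stronger l0 weight gives sparser restored gradients", {
  img <- small_star(96L)
  g <- degradeImage(img, degradationSpec(psf = gaussianPSF(9L, 1.5),
                                         noiseVariance = 1e-4, rngSeed = 5L))
  # count the auxiliary-variable support: gradients surviving the final-pass
  # hard threshold (the schedule's last threshold is 2^-3.5 for every betaF
  # because gamma0 scales with the l0 weight)
  counts <- vapply(c(0.025, 0.25, 2.5), function(b) {
    res <- restoreImage(g, gaussianPSF(9L, 1.5),
                        regularizationParams(betaF = b))
    gr <- gradForward(res$image)
    d <- hardThreshold(gr$gx, gr$gy, 2^-3.5)
    sum(d$dx != 0 | d$dy != 0)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("l1-mode GPBB objective matches a long-run projected-gradient reference", {
  set.seed(6)
  img <- random_image(8, seed = 6)
  k <- kernelWeights(gaussianPSF(3L, 0.8))
  g <- convolvePSF(img, k) + matrix(rnorm(64, sd = 0.02), 8, 8)
  reg <- regularizationParams(alpha = 500, betaF = 0.25, lambdaF = 5,
                              mode = "l1")
  cfg <- solverConfig(gpbbIterations = 40L, hqsPasses = 8L)
  res <- restoreImage(g, k, reg, cfg)
  obj_gpbb <- tail(res$trace$objective_values, 1)

  # reference: multi-start fixed-step projected gradient on the identical
  # padded periodic-domain objective
  hw <- 1L
  P <- microdeblur:::padded_dims(g, 3L)
  gpad <- reflect_pad_r(g, hw, P)
  OTF <- fft(embed_kernel_r(k, P))
  w1 <- 0.25 / 500
  eps <- 1e-4 * 1.2
  starts <- list(pmin(pmax(gpad, 0), 1.2),
                 matrix(0, P[1], P[2]),
                 matrix(0.6, P[1], P[2]))
  objs <- vapply(starts, function(s0) {
    fr <- pg_solve_l1(s0, gpad, OTF, w1, eps, 0, 1.2, iters = 1e4)
    padded_objective_l1(fr, gpad, OTF, w1, eps)
  }, numeric(1))
  expect_lt(abs(obj_gpbb - min(objs)) / min(objs), 0.01)
})

test_that("vanishing l0/l2 weights reduce restoration to box-constrained least squares", {
  img <- random_image(8, seed = 8)
  k <- kernelWeights(gaussianPSF(3L, 0.5))
  g <- convolvePSF(img, k)
  reg <- regularizationParams(alpha = 1, betaF = 1e-12, lambdaF = 0)
  res <- restoreImage(g, k, reg, solverConfig(gpbbIterations = 80L,
                                              hqsPasses = 6L,
                                              boxLow = 0, boxHigh = 1.2))
  # reference box-constrained LS by long-run projected gradient on the
  # padded domain data term (w1 = 0 -> pure least squares)
  hw <- 1L
  P <- microdeblur:::padded_dims(g, 3L)
  gpad <- reflect_pad_r(g, hw, P)
  OTF <- fft(embed_kernel_r(k, P))
  fr <- pg_solve_l1(pmin(pmax(gpad, 0), 1.2), gpad, OTF, 0, 1e-4,
                    0, 1.2, iters = 2e4)
  ref <- fr[(hw + 1):(hw + 8), (hw + 1):(hw + 8)]
  expect_equal(res$image, ref, tolerance = 1e-4)
})

test_that("restoration rejects invalid inputs", {
  img <- small_star(32L)
  expect_error(restoreImage(img, matrix(0, 3, 3)), "zero kernel")
  expect_error(restoreImage(matrix(0.5, 4, 4), gaussianPSF(5L, 1)), "larger")
})
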