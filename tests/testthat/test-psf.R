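test_that("kernel projection clips, renormalizes, recenters and is idempotent", {
  # negative entry zeroed, remainder renormalized to unit sum
  w <- matrix(c(0.2, 0.3, 0, 0.3, 0.3, 0, -0.1, 0, 0), 3, 3)
  k <- projectKernel(w)
  expect_true(all(kernelWeights(k) >= 0))
  expect_equal(sum(kernelWeights(k)), 1, tolerance = 1e-12)

  # feasible Gaussian kernel unchanged within 1e-12
  gk <- gaussianPSF(11L, 2)
  expect_equal(kernelWeights(projectKernel(gk)), kernelWeights(gk),
               tolerance = 1e-12)

  # idempotence is bit-exact
  p1 <- projectKernel(w)
  p2 <- projectKernel(p1)
  expect_identical(kernelWeights(p1), kernelWeights(p2))

  # all mass at the top-left corner shifts to the centre
  corner <- matrix(0, 5, 5)
  corner[1, 1] <- 1
  pc <- projectKernel(corner)
  expect_equal(kernelWeights(pc)[3, 3], 1)

  # all-negative kernel degenerates to a flagged centred delta
  dg <- projectKernel(matrix(-1, 3, 3))
  expect_true(dg@degenerate)
  expect_equal(kernelWeights(dg)[2, 2], 1)
})

test_that("CG kernel solution matches a dense least-squares solve on small instances", {
  img <- random_image(16, seed = 41)
  truek <- kernelWeights(gaussianPSF(5L, 1))
  obs <- convolvePSF(img, truek)
  Lf <- laplacianFilter(img)
  Lg <- laplacianFilter(obs)
  # dense operator of kernel -> Lf (*) k, via unit-kernel transforms
  P <- microdeblur:::padded_dims(img, 5L)
  A <- dense_kernel_operator(Lf, 5L, P)
  dense <- qr.solve(A, as.vector(reflect_pad_r(Lg, 2L, P)))
  cg <- microdeblur:::cpp_cg_kernel(Lf, Lg, 5L, 300L, 1e-13, P[1], P[2])
  rel <- sqrt(sum((as.vector(cg$kernel) - dense)^2)) / sqrt(sum(dense^2))
  expect_lt(rel, 1e-6)
})

test_that("identity blur yields a centred delta kernel", {
  img <- random_image(96, seed = 42)
  k <- suppressWarnings(estimatePSF(img, img, cgConfig(maxIterations = 80L,
                                                       kernelSize = 9L)))
  w <- kernelWeights(k)
  expect_lt(sum(w[-41]), 1e-3) # off-centre mass of the 9x9 kernel
})

test_that("noiseless blur recovery: fitted sigma within 0.1 and error shrinks with CG work", {
  img <- small_star(128L)
  obs <- convolvePSF(img, gaussianPSF(11L, 1.5))
  k <- suppressWarnings(estimatePSF(img, obs, cgConfig(kernelSize = 11L)))
  expect_equal(fitGaussianSigma(k), 1.5, tolerance = 0.1)

  # recovery error is non-increasing with CG work on a broader kernel,
  # where few iterations visibly under-resolve the width
  obs2 <- convolvePSF(img, gaussianPSF(15L, 2.5))
  errs <- vapply(c(5L, 15L, 40L), function(ni) {
    ki <- suppressWarnings(estimatePSF(img, obs2,
      cgConfig(maxIterations = ni, kernelSize = 15L)))
    abs(fitGaussianSigma(ki) - 2.5)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-4))
})

test_that("CG least-squares residual trace is non-increasing", {
  img <- small_star(96L)
  obs <- degradeImage(img, degradationSpec(psf = gaussianPSF(9L, 1.2),
                                           noiseVariance = 1e-4, rngSeed = 2L))
  k <- suppressWarnings(estimatePSF(img, obs, cgConfig(kernelSize = 9L)))
  res <- kernelResiduals(k)
  expect_gt(length(res), 1L)
  expect_true(all(diff(res) <= 1e-10))
})

test_that("Gaussian sigma fitting is exact on Gaussians and robust to perturbation", {
  expect_equal(fitGaussianSigma(gaussianPSF(51L, 1.5)), 1.5, tolerance = 1e-3)
  expect_equal(fitGaussianSigma(gaussianPSF(51L, 3)), 3, tolerance = 1e-3)

  w <- kernelWeights(gaussianPSF(51L, 1.5)) + 1e-4
  w <- w / sum(w)
  expect_equal(fitGaussianSigma(w), 1.5, tolerance = 0.05)

  expect_error(fitGaussianSigma(matrix(c(rep(1 / 9, 9)), 3, 3)), "flat|Gaussian")
})

test_that("estimatePSF validates its inputs", {
  img <- small_star(32L)
  expect_error(estimatePSF(img, img[1:16, 1:16], cgConfig(kernelSize = 5L)),
               "same dimensions")
  expect_error(estimatePSF(img, img, cgConfig(kernelSize = 33L)), "smaller")
})
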