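test_that("RMSE identities and symmetry", {
  a <- random_image(8, seed = 21)
  b <- random_image(8, seed = 22)
  expect_identical(imageRMSE(a, a), 0)
  expect_identical(imageRMSE(matrix(0, 4, 4), matrix(1, 4, 4)), 1)
  expect_identical(imageRMSE(a, b), imageRMSE(b, a))
  expect_error(imageRMSE(a, matrix(0, 4, 4)), "dimensions")
})

test_that("EPI is a Laplacian correlation: identity 1, inversion -1, symmetric", {
  a <- small_star(48L)
  expect_equal(edgePreservationIndex(a, a), 1)
  expect_equal(edgePreservationIndex(1 - a, a), -1)
  b <- a + 0.05 * random_image(48, seed = 23)
  expect_identical(edgePreservationIndex(b, a), edgePreservationIndex(a, b))
  expect_error(edgePreservationIndex(matrix(0.5, 8, 8), matrix(0.5, 8, 8)),
               "flat")
})

test_that("SSIM matches the per-pixel windowed formula oracle", {
  a <- random_image(16, seed = 24)
  b <- 0.7 * a + 0.3 * random_image(16, seed = 25)
  expect_equal(imageSSIM(a, b), naive_ssim(a, b), tolerance = 1e-6)
  expect_equal(imageSSIM(a, a), 1, tolerance = 1e-12)
})

test_that("PSNR closed forms and infinity sentinel", {
  ref <- matrix(0.5, 10, 10)
  # MSE 0.01 -> 20 dB
  expect_equal(imagePSNR(ref + 0.1, ref), 20)
  # MSE 1e-4 -> 40 dB
  expect_equal(imagePSNR(ref + 0.01, ref), 40)
  expect_identical(imagePSNR(ref, ref), Inf)
  a <- random_image(6, seed = 26); b <- random_image(6, seed = 27)
  expect_equal(imagePSNR(a, b), 10 * log10(1 / mean((a - b)^2)),
               tolerance = 1e-9)
})

test_that("NNPS of a perfectly flat region is zero", {
  flat <- matrix(0.5, 64, 64)
  curve <- computeNNPS(flat, npsSpec(pixelSize = 1.7, roiSize = 32L))
  expect_true(all(curve@values == 0))
})

test_that("NNPS integral satisfies Parseval: mean over bins = sigma^2 K^2 / S^2", {
  K <- 1.7; S <- 0.5; sigma2 <- 0.01
  set.seed(42)
  flat <- matrix(S + rnorm(320^2, sd = sqrt(sigma2)), 320, 320)
  spec <- npsSpec(pixelSize = K, roiSize = 32L, roiOverlap = 0.5,
                  largeAreaSignal = S)
  curve <- computeNNPS(flat, spec)
  expect_gte(curve@nROIs, 64L)
  # sum of the 2-D NNPS over all bins, divided by bin count, equals
  # sigma^2 K^2 / S^2 (white noise; ROI mean subtraction costs 1/M^2)
  integral <- mean(curve@nnps2d)
  expect_equal(integral, sigma2 * K^2 / S^2, tolerance = 0.05)
})

test_that("NNPS of white noise is radially flat", {
  set.seed(43)
  flat <- matrix(0.5 + rnorm(560^2, sd = 0.1), 560, 560)
  curve <- computeNNPS(flat, npsSpec(pixelSize = 1, roiSize = 32L,
                                     roiOverlap = 0.5))
  expect_gte(curve@nROIs, 256L)
  v <- curve@values[curve@frequencies > 0] # exclude the DC bin
  expect_lt(max(v) / min(v), 1.5)
  # frequency axis reaches Nyquist 1/(2K)
  expect_lte(max(curve@frequencies), 0.5 + 1e-12)
  expect_true(all(diff(curve@frequencies) > 0))
})

test_that("line profiles interpolate bilinearly and normalize to the maximum", {
  img <- matrix(0.8, 5, 5)
  p <- extractProfile(img, c(1, 3), c(5, 3))
  expect_true(all(p$intensity == 1))
  expect_equal(nrow(p), 5L)

  # ramp f = x: horizontal profile rises linearly to 1
  # column j has constant value (j-1)/5, so f rises along x
  ramp <- matrix(rep(seq(0, 1, length.out = 6), each = 6), 6, 6)
  pr <- extractProfile(ramp, c(1, 3), c(6, 3))
  expect_equal(pr$intensity, seq(0, 1, length.out = 6))

  # diagonal through a known 4x4 grid vs hand-computed bilinear values
  g4 <- matrix(as.numeric(1:16), 4, 4)
  pd <- extractProfile(g4, c(1, 1), c(4, 4))
  len <- sqrt(18)
  tt <- (0:4) / len
  xs <- 1 + tt * 3; ys <- 1 + tt * 3
  byhand <- vapply(seq_along(xs), function(i) {
    x0 <- min(floor(xs[i]), 3); y0 <- min(floor(ys[i]), 3)
    wx <- xs[i] - x0; wy <- ys[i] - y0
    (1 - wx) * (1 - wy) * g4[y0, x0] + wx * (1 - wy) * g4[y0, x0 + 1] +
      (1 - wx) * wy * g4[y0 + 1, x0] + wx * wy * g4[y0 + 1, x0 + 1]
  }, numeric(1))
  expect_equal(pd$intensity, byhand / max(byhand), tolerance = 1e-10)

  # degenerate all-zero profile: unnormalized, flagged
  z <- extractProfile(matrix(0, 4, 4), c(1, 1), c(4, 1))
  expect_true(isTRUE(attr(z, "degenerate")))
  expect_true(all(z$intensity == 0))
})

test_that("metric size mismatches are rejected consistently", {
  a <- matrix(0.5, 12, 12); b <- matrix(0.5, 11, 12)
  expect_error(imageRMSE(a, b), "dimensions")
  expect_error(imageSSIM(a, b), "dimensions")
  expect_error(edgePreservationIndex(a, b), "dimensions")
  expect_error(imagePSNR(a, b), "dimensions")
  expect_error(imageMismatch(a, b), "dimensions")
})
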