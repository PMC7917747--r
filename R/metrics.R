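#' Root-mean-square error
#'
#' @param a,b numeric matrices of equal size.
#' @return `sqrt(mean((a - b)^2))`; symmetric in its arguments.
#' @export
imageRMSE <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("images must have the same dimensions")
  sqrt(mean((a - b)^2))
}

#' Edge preservation index (EPI)
#'
#' Pearson correlation between the Laplacian-filtered test and reference
#' images: high-pass filtering isolates the edge content, so EPI = 1 means
#' edges perfectly preserved and negative values indicate contrast
#' inversion. Symmetric in its arguments.
#'
#' @param test,ref numeric matrices of equal size, at least 3 x 3.
#' @return scalar in `[-1, 1]`.
#' @export
edgePreservationIndex <- function(test, ref) {
  if (!identical(dim(test), dim(ref))) stop("images must have the same dimensions")
  lt <- laplacianFilter(test)
  lr <- laplacianFilter(ref)
  if (sd(lt) == 0 || sd(lr) == 0)
    stop("EPI undefined: Laplacian of a flat image has zero variance")
  cor(as.vector(lt), as.vector(lr))
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM with the canonical parameterization: 11 x 11 Gaussian
#' window with sigma 1.5, stabilizers `C1 = (0.01 L)^2`,
#' `C2 = (0.03 L)^2` with dynamic range `L = 1`. Local means, variances
#' and covariance are computed by Gaussian-weighted filtering (reflective
#' boundary) and the SSIM map is averaged over the full frame.
#'
#' @param test,ref numeric matrices of equal size, intensities nominally
#'   in `[0, 1]`.
#' @return scalar in `[-1, 1]`.
#' @export
imageSSIM <- function(test, ref) {
  if (!identical(dim(test), dim(ref))) stop("images must have the same dimensions")
  assertImage(test, min_dim = 11L)
  w <- kernelWeights(gaussianPSF(11L, 1.5))
  C1 <- 0.01^2
  C2 <- 0.03^2
  mu1 <- convolvePSF(test, w)
  mu2 <- convolvePSF(ref, w)
  s11 <- convolvePSF(test * test, w) - mu1^2
  s22 <- convolvePSF(ref * ref, w) - mu2^2
  s12 <- convolvePSF(test * ref, w) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(L^2 / MSE)` in dB with peak level `L = 1`; identical images
#' return `Inf`.
#'
#' @param test,ref numeric matrices of equal size.
#' @return PSNR in dB.
#' @export
imagePSNR <- function(test, ref) {
  if (!identical(dim(test), dim(ref))) stop("images must have the same dimensions")
  mse <- mean((test - ref)^2)
  if (mse == 0) return(Inf)
  10 * log10(1 / mse)
}

#' NNPS estimation protocol
#'
#' @param pixelSize detector pixel size K in um.
#' @param roiSize ROI side length in pixels, a power of two (default 128).
#' @param roiOverlap fractional overlap of successive ROIs in `[0, 1)`
#'   (default 0.5).
#' @param largeAreaSignal large-area signal S used for normalization;
#'   `NULL` (default) uses the mean of the analysed region.
#' @return classed list for [computeNNPS()].
#' @export
npsSpec <- function(pixelSize, roiSize = 128L, roiOverlap = 0.5,
                    largeAreaSignal = NULL) {
  roiSize <- as.integer(roiSize)
  if (pixelSize <= 0) stop("'pixelSize' must be positive")
  if (roiSize < 2L || bitwAnd(roiSize, roiSize - 1L) != 0L)
    stop("'roiSize' must be a power of two")
  if (roiOverlap < 0 || roiOverlap >= 1) stop("'roiOverlap' must be in [0, 1)")
  if (!is.null(largeAreaSignal) && largeAreaSignal <= 0)
    stop("'largeAreaSignal' must be positive")
  structure(list(pixelSize = pixelSize, roiSize = roiSize,
                 roiOverlap = roiOverlap, largeAreaSignal = largeAreaSignal),
            class = "NPSSpec")
}

#' Normalized noise power spectrum of a flat-field region
#'
#' Tiles the region into overlapping ROIs, subtracts each ROI's mean
#' (detrending), averages the squared modulus of the 2-D Fourier transform
#' over ROIs and scales by `K^2 / roiSize^2` to obtain the noise power
#' spectrum NPS(u, v) (the standard detector-NPS estimator; its integral
#' over frequency equals the noise variance). Division by the squared
#' large-area signal gives the NNPS, which is then radially averaged into
#' a 1-D curve with the frequency axis in lp/um up to the Nyquist
#' frequency `1/(2K)`.
#'
#' @param flatRegion numeric matrix, a nominally uniform (noise-only)
#'   region at least `roiSize` on each side.
#' @param spec an [npsSpec()].
#' @return an [NNPSCurve-class]
#' @export
computeNNPS <- function(flatRegion, spec) {
  stopifnot(inherits(spec, "NPSSpec"))
  assertImage(flatRegion)
  M <- spec$roiSize
  if (nrow(flatRegion) < M || ncol(flatRegion) < M)
    stop("flat region is smaller than the ROI size")
  K <- spec$pixelSize
  step <- max(1L, as.integer(round(M * (1 - spec$roiOverlap))))
  starts_i <- unique(pmin(seq(1L, nrow(flatRegion) - M + 1L, by = step),
                          nrow(flatRegion) - M + 1L))
  starts_j <- unique(pmin(seq(1L, ncol(flatRegion) - M + 1L, by = step),
                          ncol(flatRegion) - M + 1L))
  acc <- matrix(0, M, M)
  n_roi <- 0L
  for (i0 in starts_i) {
    for (j0 in starts_j) {
      roi <- flatRegion[i0:(i0 + M - 1L), j0:(j0 + M - 1L)]
      roi <- roi - mean(roi)
      acc <- acc + Mod(fft(roi))^2
      n_roi <- n_roi + 1L
    }
  }
  nps <- (K^2 / M^2) * acc / n_roi
  S <- if (is.null(spec$largeAreaSignal)) mean(flatRegion) else spec$largeAreaSignal
  if (S == 0) stop("large-area signal is zero; NNPS undefined")
  nnps <- nps / S^2
  # radial average on the centred frequency grid, bin width 1/(M K)
  fu <- c(0:(M / 2), -(M / 2 - 1):-1) / (M * K)
  fr <- sqrt(outer(fu^2, fu^2, "+"))
  df <- 1 / (M * K)
  nyq <- 1 / (2 * K)
  bin <- round(fr / df)
  keep <- bin * df <= nyq + 1e-12
  means <- tapply(nnps[keep], bin[keep], mean)
  freqs <- as.numeric(names(means)) * df
  ord <- order(freqs)
  new("NNPSCurve", frequencies = freqs[ord],
      values = pmax(as.numeric(means)[ord], 0),
      pixelSize = K, nnps2d = nnps, nROIs = n_roi)
}

#' Extract a max-normalized line profile
#'
#' Samples the image by bilinear interpolation at unit-spaced points along
#' the segment from `start` to `end` (both `c(x, y)` in pixel coordinates,
#' x = column, y = row) and divides by the profile maximum. An all-zero
#' profile is returned unnormalized with attribute `degenerate = TRUE`.
#'
#' @param img numeric matrix.
#' @param start,end numeric length-2 endpoints inside the image.
#' @return data.frame with columns `position` (pixels along the segment)
#'   and `intensity` (max-normalized).
#' @export
extractProfile <- function(img, start, end) {
  assertImage(img)
  check_pt <- function(p, nm) {
    if (length(p) != 2L || p[1] < 1 || p[1] > ncol(img) ||
        p[2] < 1 || p[2] > nrow(img))
      stop(sprintf("'%s' must be c(x, y) inside the image", nm))
  }
  check_pt(start, "start")
  check_pt(end, "end")
  len <- sqrt(sum((end - start)^2))
  pos <- seq(0, floor(len))
  tt <- if (len > 0) pos / len else 0
  xs <- start[1] + tt * (end[1] - start[1])
  ys <- start[2] + tt * (end[2] - start[2])
  x0 <- pmin(floor(xs), ncol(img) - 1L); x0 <- pmax(x0, 1L)
  y0 <- pmin(floor(ys), nrow(img) - 1L); y0 <- pmax(y0, 1L)
  wx <- xs - x0
  wy <- ys - y0
  idx <- function(r, c) img[cbind(r, c)]
  vals <- (1 - wx) * (1 - wy) * idx(y0, x0) +
    wx * (1 - wy) * idx(y0, x0 + 1L) +
    (1 - wx) * wy * idx(y0 + 1L, x0) +
    wx * wy * idx(y0 + 1L, x0 + 1L)
  m <- max(vals)
  if (m <= 0) {
    out <- data.frame(position = pos, intensity = vals)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  data.frame(position = pos, intensity = vals / m)
}
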