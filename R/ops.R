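## Core image operators shared by the simulator, the kernel estimator and
## the restoration solver.

assertImage <- function(img, min_dim = 3L, arg = deparse(substitute(img))) {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("'%s' must be a numeric matrix", arg))
  if (nrow(img) < min_dim || ncol(img) < min_dim)
    stop(sprintf("'%s' must be at least %dx%d", arg, min_dim, min_dim))
  if (any(!is.finite(img)))
    stop(sprintf("'%s' contains non-finite values", arg))
  invisible(img)
}

as_kernel_matrix <- function(k) {
  if (is(k, "PSFKernel")) k <- k@weights
  if (!is.matrix(k) || !is.numeric(k)) stop("kernel must be a numeric matrix or PSFKernel")
  if (nrow(k) != ncol(k)) stop("kernel must be square")
  if (nrow(k) %% 2 != 1) stop("kernel side length must be odd")
  k
}

# FFT-friendly (2,3,5-smooth) periodic domain for an image padded by the
# kernel half-width on each side
padded_dims <- function(img, ksize) {
  hw <- (ksize - 1L) %/% 2L
  c(nextn(nrow(img) + 2L * hw, c(2L, 3L, 5L)),
    nextn(ncol(img) + 2L * hw, c(2L, 3L, 5L)))
}

#' Construct a PSFKernel from a weight matrix
#'
#' Validates feasibility (square, odd side, non-negative, unit sum). Use
#' [projectKernel()] to map an arbitrary matrix onto the feasible set first.
#'
#' @param weights square numeric matrix with odd side length.
#' @return a [PSFKernel-class]
#' @export
psfKernel <- function(weights) {
  new("PSFKernel", weights = as_kernel_matrix(weights))
}

#' Gaussian point-spread function
#'
#' An isotropic Gaussian kernel sampled at pixel centres and normalized to
#' unit sum; the parametric PSF model used throughout the simulation study
#' (default 51 x 51 pixels, sigma 1.5 pixels).
#'
#' @param size odd kernel side length in pixels.
#' @param sigma Gaussian standard deviation in pixels.
#' @return a [PSFKernel-class]
#' @examples
#' k <- gaussianPSF(51, 1.5)
#' fitGaussianSigma(k) # ~1.5
#' @export
gaussianPSF <- function(size = 51L, sigma = 1.5) {
  size <- as.integer(size)
  if (size %% 2L != 1L || size < 1L) stop("'size' must be a positive odd integer")
  if (sigma <= 0) stop("'sigma' must be positive")
  hw <- (size - 1L) %/% 2L
  x <- seq(-hw, hw)
  g <- exp(-x^2 / (2 * sigma^2))
  w <- outer(g, g)
  psfKernel(w / sum(w))
}

#' Delta (identity) kernel
#'
#' @param size odd side length.
#' @return a [PSFKernel-class] with all mass at the centre pixel.
#' @export
deltaPSF <- function(size = 3L) {
  size <- as.integer(size)
  if (size %% 2L != 1L) stop("'size' must be odd")
  w <- matrix(0, size, size)
  w[(size + 1L) %/% 2L, (size + 1L) %/% 2L] <- 1
  psfKernel(w)
}

#' 2-D convolution with a PSF
#'
#' Convolves an image with a kernel using FFT evaluation on a periodic
#' domain after reflective pre-padding by the kernel half-width, then crops
#' back, so the output has the same size as the input and no wraparound
#' artefacts. Linear in the image.
#'
#' @param img numeric matrix.
#' @param k a [PSFKernel-class] or square odd-sized numeric matrix.
#' @return numeric matrix, same dimensions as `img`.
#' @examples
#' x <- matrix(runif(36), 6, 6)
#' all.equal(convolvePSF(x, deltaPSF(3)), x)
#' @export
convolvePSF <- function(img, k) {
  assertImage(img, min_dim = 1L)
  k <- as_kernel_matrix(k)
  if (nrow(k) > nrow(img) || ncol(k) > ncol(img))
    stop("kernel must not be larger than the image")
  P <- padded_dims(img, nrow(k))
  cpp_fft_conv2(img, k, P[1], P[2])
}

#' Discrete Laplacian
#'
#' The 3 x 3 five-point stencil `[[0,1,0],[1,-4,1],[0,1,0]]` with reflective
#' (mirror) boundary handling; annihilates constant and affine images in the
#' interior. Used both by the kernel estimator (which matches Laplacian
#' images) and by the edge preservation index.
#'
#' @param img numeric matrix, at least 3 x 3.
#' @return numeric matrix, same dimensions.
#' @export
laplacianFilter <- function(img) {
  assertImage(img, min_dim = 3L)
  cpp_laplacian(img)
}

#' Forward-difference gradient
#'
#' Forward differences along x (columns) and y (rows) with the last
#' column/row replicated, i.e. zero gradient at the far boundary.
#'
#' @param img numeric matrix, at least 2 x 2.
#' @return list with components `gx` and `gy`, each the size of `img`.
#' @export
gradForward <- function(img) {
  assertImage(img, min_dim = 2L)
  n1 <- nrow(img); n2 <- ncol(img)
  gx <- img[, c(2:n2, n2), drop = FALSE] - img
  gy <- img[c(2:n1, n1), , drop = FALSE] - img
  list(gx = gx, gy = gy)
}

#' Group hard threshold on a gradient field
#'
#' Per pixel, the gradient pair (gx, gy) is kept when its Euclidean
#' magnitude is at least `threshold` (ties kept), otherwise both components
#' are set to zero. This is the closed-form auxiliary step realizing the l0
#' gradient penalty inside the half-quadratic splitting.
#'
#' @param gx,gy numeric matrices of equal size.
#' @param threshold non-negative scalar.
#' @return list with thresholded components `dx`, `dy`.
#' @export
hardThreshold <- function(gx, gy, threshold) {
  if (!identical(dim(gx), dim(gy))) stop("gx and gy must have the same dimensions")
  if (threshold < 0) stop("'threshold' must be non-negative")
  keep <- (gx^2 + gy^2) >= threshold^2
  list(dx = gx * keep, dy = gy * keep)
}
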