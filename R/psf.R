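#' Inner-solver configuration for PSF estimation
#'
#' @param maxIterations conjugate-gradient iteration cap (default 25).
#' @param residualTolerance relative residual at which CG stops
#'   (default 1e-6).
#' @param kernelSize odd support size of the estimated kernel (default 51).
#' @return classed list for [estimatePSF()].
#' @export
cgConfig <- function(maxIterations = 25L, residualTolerance = 1e-6,
                     kernelSize = 51L) {
  maxIterations <- as.integer(maxIterations)
  kernelSize <- as.integer(kernelSize)
  if (maxIterations < 1L) stop("'maxIterations' must be at least 1")
  if (residualTolerance <= 0) stop("'residualTolerance' must be positive")
  if (kernelSize %% 2L != 1L) stop("'kernelSize' must be odd")
  structure(list(maxIterations = maxIterations,
                 residualTolerance = residualTolerance,
                 kernelSize = kernelSize), class = "CGConfig")
}

#' Estimate the blur kernel by conjugate gradients on Laplacian images
#'
#' Finds the kernel k of the configured support minimizing
#' `|| L(current) (*) k - L(observed) ||^2`, where `L` is the discrete
#' Laplacian and `(*)` 2-D convolution, by conjugate gradients on the
#' normal equations of the linear operator `k -> L(current) (*) k` (whose
#' adjoint is correlation with `L(current)`). Working on Laplacian-filtered
#' images suppresses the flat-field content that otherwise dominates the
#' fit and makes the estimation robust to smooth intensity trends. The
#' result is projected onto the feasible kernel set (non-negative, unit
#' sum, centred) by [projectKernel()].
#'
#' Non-convergence (residual above tolerance at the iteration cap) is
#' signalled through the `converged` flag of the returned kernel, not an
#' error.
#'
#' @param current numeric matrix, the current latent image estimate.
#' @param observed numeric matrix, the degraded observation (same size).
#' @param config a [cgConfig()].
#' @return a [PSFKernel-class] carrying the residual trace.
#' @examples
#' f <- generateStarPhantom(starPhantomSpec(imageSize = 96L))
#' g <- convolvePSF(f, gaussianPSF(9L, 1.2))
#' k <- estimatePSF(f, g, cgConfig(kernelSize = 9L))
#' fitGaussianSigma(k) # ~1.2
#' @export
estimatePSF <- function(current, observed, config = cgConfig()) {
  stopifnot(inherits(config, "CGConfig"))
  assertImage(current)
  assertImage(observed)
  if (!identical(dim(current), dim(observed)))
    stop("'current' and 'observed' must have the same dimensions")
  if (config$kernelSize >= min(dim(current)))
    stop("'kernelSize' must be smaller than both image dimensions")
  Lf <- cpp_laplacian(current)
  Lg <- cpp_laplacian(observed)
  P <- padded_dims(current, config$kernelSize)
  fit <- cpp_cg_kernel(Lf, Lg, config$kernelSize, config$maxIterations,
                       config$residualTolerance, P[1], P[2])
  if (!fit$converged)
    warning("CG kernel estimation stopped at the iteration cap above tolerance")
  k <- projectKernel(fit$kernel)
  k@converged <- fit$converged
  k@residuals <- as.numeric(fit$residuals)
  k
}

#' Project a kernel onto the feasible set
#'
#' Negative weights are set to zero, the weights are renormalized to unit
#' sum, and the mass centroid is re-centred onto the central pixel by an
#' integer shift (with zero fill). If thresholding removes all mass the
#' centred delta kernel is returned with the `degenerate` flag set.
#' Idempotent on the feasible set.
#'
#' @param k a [PSFKernel-class] or square odd-sized numeric matrix.
#' @return a [PSFKernel-class]
#' @export
projectKernel <- function(k) {
  w <- if (is(k, "PSFKernel")) k@weights else k
  if (!is.matrix(w) || nrow(w) != ncol(w) || nrow(w) %% 2L != 1L)
    stop("kernel must be a square odd-sized matrix")
  s <- nrow(w)
  c0 <- (s + 1L) %/% 2L
  w[w < 0] <- 0
  if (sum(w) <= 0) {
    out <- deltaPSF(s)
    out@degenerate <- TRUE
    return(out)
  }
  w <- w / sum(w)
  ci <- sum(row(w) * w)
  cj <- sum(col(w) * w)
  di <- round(c0 - ci)
  dj <- round(c0 - cj)
  if (di != 0 || dj != 0) {
    shifted <- matrix(0, s, s)
    src_i <- seq_len(s) - di
    src_j <- seq_len(s) - dj
    ok_i <- src_i >= 1L & src_i <= s
    ok_j <- src_j >= 1L & src_j <= s
    shifted[ok_i, ok_j] <- w[src_i[ok_i], src_j[ok_j]]
    if (sum(shifted) <= 0) {
      out <- deltaPSF(s)
      out@degenerate <- TRUE
      return(out)
    }
    w <- shifted / sum(shifted)
  }
  new("PSFKernel", weights = w)
}

#' Fit a 1-D Gaussian sigma to a kernel's central profile
#'
#' Least-squares fit of `A * exp(-x^2 / (2 sigma^2))` (amplitude and sigma,
#' centre fixed at the kernel centre) to the central row profile through
#' the kernel centre, mirroring how estimated PSFs are quantified against
#' the generating Gaussian by a line profile through the kernel. Returns
#' sigma in pixels.
#'
#' @param k a [PSFKernel-class] or square odd-sized numeric matrix.
#' @return fitted sigma (pixels).
#' @export
fitGaussianSigma <- function(k) {
  w <- as_kernel_matrix(k)
  if (sum(w) <= 0) stop("kernel sum must be positive")
  s <- nrow(w)
  c0 <- (s + 1L) %/% 2L
  y <- w[c0, ]
  x <- seq_len(s) - c0
  if (max(y) <= 0 || sd(y) == 0)
    stop("central profile is flat; kernel is not Gaussian-like")
  # moment-based start for sigma
  pos <- y > 0
  s0 <- sqrt(sum(y[pos] * x[pos]^2) / sum(y[pos]))
  if (!is.finite(s0) || s0 <= 0) s0 <- s / 6
  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-x^2 / (2 * sigma^2)), data = df,
                      start = list(A = max(y), sigma = s0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Gaussian fit failed; kernel is not Gaussian-like: ",
                             conditionMessage(e))
  )
  sigma <- abs(unname(coef(fit)["sigma"]))
  if (!is.finite(sigma) || sigma <= 0)
    stop("Gaussian fit returned a non-positive sigma; kernel is not Gaussian-like")
  sigma
}
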