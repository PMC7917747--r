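#' Siemens-star phantom specification
#'
#' Parameters of the numerical resolution phantom: a disc of alternating
#' bright/dark angular sectors (spokes) whose spacing shrinks towards the
#' centre, probing resolution as a function of spatial frequency. Defaults
#' reproduce the simulation study geometry: a 2000 x 2000 pixel frame with
#' 36 spoke pairs, star diameter 0.9 of the frame, mid-gray background, and
#' a pixel pitch of 1.7 um recorded as metadata.
#'
#' @param imageSize pixels per side of the (square) frame.
#' @param nSpokePairs number of bright/dark sector pairs (>= 1).
#' @param starDiameter star disc diameter in pixels (default 0.9 * imageSize).
#' @param brightLevel,darkLevel,backgroundLevel intensities in `[0, 1]`;
#'   `brightLevel` must exceed `darkLevel`.
#' @param supersampleFactor integer >= 1; each pixel is rendered as the box
#'   average of `supersampleFactor^2` sub-samples to anti-alias the
#'   sub-pixel spoke edges near the centre.
#' @param pixelPitch physical pixel size in um (metadata; used by NNPS
#'   frequency axes only).
#' @return a validated spec (classed list) for [generateStarPhantom()].
#' @export
starPhantomSpec <- function(imageSize = 2000L, nSpokePairs = 36L,
                            starDiameter = 0.9 * imageSize,
                            brightLevel = 1, darkLevel = 0,
                            backgroundLevel = 0.5,
                            supersampleFactor = 4L,
                            pixelPitch = 1.7) {
  imageSize <- as.integer(imageSize)
  nSpokePairs <- as.integer(nSpokePairs)
  supersampleFactor <- as.integer(supersampleFactor)
  if (nSpokePairs < 1L) stop("'nSpokePairs' must be at least 1")
  if (starDiameter > imageSize) stop("'starDiameter' must not exceed 'imageSize'")
  if (starDiameter <= 0) stop("'starDiameter' must be positive")
  if (brightLevel <= darkLevel) stop("'brightLevel' must exceed 'darkLevel'")
  if (supersampleFactor < 1L) stop("'supersampleFactor' must be at least 1")
  structure(list(
    imageSize = imageSize, nSpokePairs = nSpokePairs,
    starDiameter = starDiameter, brightLevel = brightLevel,
    darkLevel = darkLevel, backgroundLevel = backgroundLevel,
    supersampleFactor = supersampleFactor, pixelPitch = pixelPitch
  ), class = "StarPhantomSpec")
}

#' Generate the Siemens-star reference phantom
#'
#' Renders the star test chart deterministically: inside the star disc the
#' intensity alternates between `brightLevel` and `darkLevel` in
#' `nSpokePairs` angular periods (a sector is bright iff
#' `sin(nSpokePairs * theta) > 0`, where `theta = atan2(y - cy, x - cx)`
#' with x the column and y the row index); outside the disc the image is
#' uniform `backgroundLevel`. Rendering is anti-aliased by box-averaging
#' `supersampleFactor^2` sub-pixel samples.
#'
#' @param spec a [starPhantomSpec()].
#' @return numeric matrix of size `imageSize x imageSize` with the pixel
#'   pitch attached as attribute `pixelPitch` (um).
#' @examples
#' star <- generateStarPhantom(starPhantomSpec(imageSize = 128L))
#' @export
generateStarPhantom <- function(spec = starPhantomSpec()) {
  stopifnot(inherits(spec, "StarPhantomSpec"))
  n <- spec$imageSize
  ss <- spec$supersampleFactor
  centre <- (n + 1) / 2
  radius <- spec$starDiameter / 2
  # sub-pixel sample coordinates for one axis: pixel j sampled at
  # j - 0.5 + (k - 0.5)/ss, k = 1..ss
  coords <- function(idx) {
    as.vector(t(outer(idx, (seq_len(ss) - 0.5) / ss - 0.5, "+")))
  }
  xs <- coords(seq_len(n)) - centre
  out <- matrix(spec$backgroundLevel, n, n)
  block <- max(1L, floor(4e6 / (n * ss * ss)))  # rows per block, bounded work set
  row_starts <- seq(1L, n, by = block)
  for (r0 in row_starts) {
    rows <- r0:min(r0 + block - 1L, n)
    ys <- coords(rows) - centre
    dx <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
    dy <- matrix(ys, nrow = length(ys), ncol = length(xs))
    inside <- (dx * dx + dy * dy) <= radius * radius
    val <- matrix(spec$backgroundLevel, length(ys), length(xs))
    if (any(inside)) {
      theta <- atan2(dy[inside], dx[inside])
      val[inside] <- ifelse(sin(spec$nSpokePairs * theta) > 0,
                            spec$brightLevel, spec$darkLevel)
    }
    # box-average ss x ss blocks back to pixel resolution
    if (ss > 1L) {
      a <- matrix(colMeans(matrix(val, nrow = ss)), nrow = length(rows))
      b <- t(matrix(colMeans(matrix(t(a), nrow = ss)), nrow = n))
      out[rows, ] <- b
    } else {
      out[rows, ] <- val
    }
  }
  attr(out, "pixelPitch") <- spec$pixelPitch
  out
}

#' Degradation specification
#'
#' The forward model applied to a clean image: convolution with a PSF plus
#' i.i.d. additive Gaussian noise. `noiseVariance` is the variance of the
#' noise in squared intensity units. The default emulates the simulated
#' light-microscopy acquisition this package reproduces: a 51 x 51 Gaussian
#' PSF of sigma 1.5 px and ~1 percent sensor noise (sd 0.01 on `[0, 1]`
#' intensities, variance 1e-4) — the noise amplitude consistent with the
#' degraded-image edge metrics that acquisition reports; see the methods
#' vignette for the reasoning.
#'
#' @param psf a [PSFKernel-class] (default 51 x 51 Gaussian, sigma 1.5).
#' @param noiseMean noise mean (intensity).
#' @param noiseVariance noise variance (intensity^2), >= 0; default 1e-4.
#' @param rngSeed integer seed making the noise field reproducible.
#' @return classed list for [degradeImage()].
#' @export
degradationSpec <- function(psf = gaussianPSF(51L, 1.5), noiseMean = 0,
                            noiseVariance = 1e-4, rngSeed = 0L) {
  if (noiseVariance < 0) stop("'noiseVariance' must be non-negative")
  psf <- if (is(psf, "PSFKernel")) psf else psfKernel(psf)
  structure(list(psf = psf, noiseMean = noiseMean,
                 noiseVariance = noiseVariance, rngSeed = as.integer(rngSeed)),
            class = "DegradationSpec")
}

#' Apply the forward degradation model
#'
#' Returns `convolvePSF(clean, psf) + N` with `N` i.i.d. Gaussian noise of
#' the configured mean and variance, drawn reproducibly from `rngSeed`
#' without disturbing the caller's RNG state. The output is deliberately
#' NOT clipped to `[0, 1]`: clipping would bias the additive noise model
#' (clip only for display or 8/16-bit export).
#'
#' @param clean numeric matrix.
#' @param spec a [degradationSpec()].
#' @return numeric matrix, same size as `clean`.
#' @export
degradeImage <- function(clean, spec = degradationSpec()) {
  stopifnot(inherits(spec, "DegradationSpec"))
  assertImage(clean)
  k <- kernelWeights(spec$psf)
  if (nrow(k) > nrow(clean) || ncol(k) > ncol(clean))
    stop("kernel must not be larger than the image")
  blurred <- convolvePSF(clean, k)
  if (spec$noiseVariance == 0 && spec$noiseMean == 0) return(blurred)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$rngSeed)
  noise <- matrix(rnorm(length(clean), mean = spec$noiseMean,
                        sd = sqrt(spec$noiseVariance)),
                  nrow(clean), ncol(clean))
  blurred + noise
}
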