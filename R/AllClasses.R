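#' @useDynLib microdeblur, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats cor fft nextn rnorm sd coef
NULL

#' PSFKernel: a feasible blur kernel
#'
#' A small, square, odd-sized convolution kernel representing the
#' point-spread function (PSF) of the imaging system: non-negative weights
#' summing to one. Kernels produced by [estimatePSF()] carry their
#' conjugate-gradient residual trace and a convergence flag.
#'
#' @slot weights numeric matrix, square with odd side, non-negative,
#'   summing to 1 (within 1e-9).
#' @slot converged logical; for estimated kernels, whether the inner solver
#'   reached its residual tolerance.
#' @slot residuals numeric; relative least-squares residual per solver
#'   iteration (empty for analytically constructed kernels).
#' @slot degenerate logical; `TRUE` when projection had to fall back to a
#'   centred delta because all mass was thresholded away.
#'
#' @seealso [psfKernel()], [gaussianPSF()], [projectKernel()],
#'   [fitGaussianSigma()]
#' @export
setClass("PSFKernel",
  representation(
    weights = "matrix",
    converged = "logical",
    residuals = "numeric",
    degenerate = "logical"
  ),
  prototype(converged = TRUE, residuals = numeric(0), degenerate = FALSE)
)

setValidity("PSFKernel", function(object) {
  w <- object@weights
  if (!is.numeric(w)) return("weights must be numeric")
  if (nrow(w) != ncol(w)) return("kernel must be square")
  if (nrow(w) %% 2 != 1) return("kernel side length must be odd")
  if (any(!is.finite(w))) return("kernel weights must be finite")
  if (any(w < 0)) return("kernel weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) return("kernel weights must sum to 1 (within 1e-9)")
  TRUE
})

#' BlindDeconvResult: output of the alternating blind-deconvolution loop
#'
#' One entry per colour channel (grayscale input gives a single entry):
#' the restored image, the estimated [PSFKernel-class], the number of outer
#' alternations used, the history of inter-iterate mismatches, and a
#' convergence flag.
#'
#' @slot restored list of numeric matrices, one restored channel each.
#' @slot kernels list of [PSFKernel-class] objects, one per channel.
#' @slot outerIterations integer vector; outer alternations used per channel.
#' @slot mismatchHistory list of numeric vectors; relative L2 mismatch
#'   between successive restored iterates, one value per outer iteration.
#' @slot converged logical vector per channel.
#'
#' @seealso [blindDeconvolve()]
#' @export
setClass("BlindDeconvResult",
  representation(
    restored = "list",
    kernels = "list",
    outerIterations = "integer",
    mismatchHistory = "list",
    converged = "logical"
  )
)

setValidity("BlindDeconvResult", function(object) {
  nc <- length(object@restored)
  if (length(object@kernels) != nc) return("one kernel per channel required")
  if (length(object@outerIterations) != nc) return("one iteration count per channel")
  if (length(object@mismatchHistory) != nc) return("one mismatch history per channel")
  if (length(object@converged) != nc) return("one convergence flag per channel")
  for (i in seq_len(nc)) {
    h <- object@mismatchHistory[[i]]
    if (length(h) != object@outerIterations[i])
      return("mismatch history length must equal outer iterations used")
    if (any(h <= 0)) return("mismatch history must be strictly positive")
  }
  TRUE
})

#' NNPSCurve: radially averaged normalized noise power spectrum
#'
#' The 1-D radial average of the 2-D normalized noise power spectrum (NNPS)
#' of a flat-field region, with the spatial-frequency axis in line pairs per
#' micrometre (lp/um) up to the Nyquist frequency 1/(2K) for pixel size K.
#' The 2-D NNPS and the ROI count used for averaging are retained for
#' integral (Parseval) checks.
#'
#' @slot frequencies numeric; bin-centre spatial frequencies (lp/um),
#'   non-negative and strictly increasing.
#' @slot values numeric; radially averaged NNPS per bin (um^2, normalized).
#' @slot pixelSize numeric; detector pixel size K in um.
#' @slot nnps2d numeric matrix; the full 2-D NNPS (fftshifted not applied).
#' @slot nROIs integer; number of ROIs averaged.
#'
#' @seealso [computeNNPS()]
#' @export
setClass("NNPSCurve",
  representation(
    frequencies = "numeric",
    values = "numeric",
    pixelSize = "numeric",
    nnps2d = "matrix",
    nROIs = "integer"
  )
)

setValidity("NNPSCurve", function(object) {
  f <- object@frequencies
  if (any(f < 0)) return("frequencies must be non-negative")
  if (length(f) > 1 && any(diff(f) <= 0)) return("frequencies must be strictly increasing")
  if (length(f) != length(object@values)) return("frequencies and values must align")
  if (any(object@values < -1e-15)) return("NNPS values must be non-negative")
  TRUE
})
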