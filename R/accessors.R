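#' Accessors for PSFKernel
#'
#' @param x a [PSFKernel-class]
#' @return `kernelWeights` returns the weight matrix, `kernelSize` the odd
#'   side length, `kernelConverged` the inner-solver convergence flag and
#'   `kernelResiduals` the residual trace.
#' @export
kernelWeights <- function(x) {
  stopifnot(is(x, "PSFKernel"))
  x@weights
}

#' @rdname kernelWeights
#' @export
kernelSize <- function(x) {
  stopifnot(is(x, "PSFKernel"))
  nrow(x@weights)
}

#' @rdname kernelWeights
#' @export
kernelConverged <- function(x) {
  stopifnot(is(x, "PSFKernel"))
  x@converged
}

#' @rdname kernelWeights
#' @export
kernelResiduals <- function(x) {
  stopifnot(is(x, "PSFKernel"))
  x@residuals
}

#' Accessors for BlindDeconvResult
#'
#' @param x a [BlindDeconvResult-class]
#' @return `restoredImages` returns the list of restored channel matrices,
#'   `estimatedKernels` the list of per-channel [PSFKernel-class] objects,
#'   `mismatchHistory` the per-channel mismatch traces, `outerIterations`
#'   the alternation counts and `isConverged` the per-channel flags.
#' @export
restoredImages <- function(x) {
  stopifnot(is(x, "BlindDeconvResult"))
  x@restored
}

#' @rdname restoredImages
#' @export
estimatedKernels <- function(x) {
  stopifnot(is(x, "BlindDeconvResult"))
  x@kernels
}

#' @rdname restoredImages
#' @export
mismatchHistory <- function(x) {
  stopifnot(is(x, "BlindDeconvResult"))
  x@mismatchHistory
}

#' @rdname restoredImages
#' @export
outerIterations <- function(x) {
  stopifnot(is(x, "BlindDeconvResult"))
  x@outerIterations
}

#' @rdname restoredImages
#' @export
isConverged <- function(x) {
  stopifnot(is(x, "BlindDeconvResult"))
  x@converged
}

#' @describeIn computeNNPS coerce the radial curve to a data.frame with
#'   columns `frequency` (lp/um) and `nnps`.
#' @param x an [NNPSCurve-class]
#' @param ... ignored
#' @export
#' @method as.data.frame NNPSCurve
as.data.frame.NNPSCurve <- function(x, ...) {
  data.frame(frequency = x@frequencies, nnps = x@values)
}

setMethod("show", "PSFKernel", function(object) {
  cat(sprintf(
    "PSFKernel %dx%d | sum = %.6f | converged = %s%s\n",
    nrow(object@weights), ncol(object@weights), sum(object@weights),
    object@converged, if (object@degenerate) " | DEGENERATE (delta fallback)" else ""
  ))
  if (length(object@residuals))
    cat(sprintf("  final relative residual: %.3g (%d CG iterations)\n",
                object@residuals[length(object@residuals)],
                length(object@residuals)))
})

setMethod("show", "BlindDeconvResult", function(object) {
  nc <- length(object@restored)
  cat(sprintf("BlindDeconvResult with %d channel(s)\n", nc))
  for (i in seq_len(nc)) {
    h <- object@mismatchHistory[[i]]
    cat(sprintf(
      "  channel %d: %dx%d, %d outer iteration(s), final mismatch %.3g, converged = %s\n",
      i, nrow(object@restored[[i]]), ncol(object@restored[[i]]),
      object@outerIterations[i],
      if (length(h)) h[length(h)] else NA_real_, object@converged[i]
    ))
  }
})

setMethod("show", "NNPSCurve", function(object) {
  cat(sprintf(
    "NNPSCurve: %d radial bins, pixel size %.3g um, Nyquist %.3g lp/um, %d ROIs\n",
    length(object@frequencies), object@pixelSize,
    1 / (2 * object@pixelSize), object@nROIs
  ))
})
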