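#' Regularization parameters for non-blind restoration
#'
#' The restoration objective is
#' `(alpha/2) ||f (*) k - g||^2 + R(f)` minimized over a box, with
#' `R(f) = betaF ||grad f||_0 + lambdaF betaF ||grad f||_2^2` in
#' `bi-l0-l2` mode (an l0 count of nonzero gradients enforcing edge
#' sparsity plus an l2 gradient energy suppressing noise) or
#' `R(f) = betaF ||grad f||_1` (anisotropic) in `l1` comparison mode.
#' `alpha` is the fidelity/regularization trade-off; larger values trust
#' the data more. Defaults are the study values alpha = 500,
#' betaF = 0.25, lambdaF = 5.
#'
#' @param alpha positive fidelity weight (default 500).
#' @param betaF positive l0 / l1 gradient weight (default 0.25).
#' @param lambdaF non-negative relative weight of the l2 gradient term
#'   (default 5).
#' @param mode `"bi-l0-l2"` or `"l1"`.
#' @return classed list for [restoreImage()].
#' @export
regularizationParams <- function(alpha = 500, betaF = 0.25, lambdaF = 5,
                                 mode = c("bi-l0-l2", "l1")) {
  mode <- match.arg(mode)
  if (alpha <= 0) stop("'alpha' must be positive")
  if (betaF <= 0) stop("'betaF' must be positive")
  if (lambdaF < 0) stop("'lambdaF' must be non-negative")
  structure(list(alpha = alpha, betaF = betaF, lambdaF = lambdaF, mode = mode),
            class = "RegularizationParams")
}

#' Solver configuration for the GPBB / half-quadratic splitting solver
#'
#' The l0 gradient count is handled by half-quadratic splitting: an
#' auxiliary gradient field d is obtained in closed form by group hard
#' thresholding, and the remaining smooth quadratic is solved by gradient
#' projection with Barzilai-Borwein (BB1) step lengths. The splitting
#' weight gamma starts at `hqsGamma0` (default `2 * betaF / alpha`, which
#' makes the first hard threshold equal to the unit dynamic range) and is
#' multiplied by `hqsGammaGrowth` each pass, progressively admitting finer
#' edges.
#'
#' @param gpbbIterations BB iterations per f-step (default 20).
#' @param hqsPasses number of splitting passes (default 8).
#' @param hqsGamma0 initial splitting weight; `NULL` selects
#'   `2 * betaF / alpha`.
#' @param hqsGammaGrowth multiplicative gamma schedule, > 1 (default 2).
#' @param boxLow,boxHigh feasible intensity box during iteration (default
#'   `[0, 1.2]`: slightly loose above 1 so noise overshoot does not lock
#'   onto the boundary; clip to `[0, 1]` only at export).
#' @return classed list for [restoreImage()].
#' @export
solverConfig <- function(gpbbIterations = 20L, hqsPasses = 8L,
                         hqsGamma0 = NULL, hqsGammaGrowth = 2,
                         boxLow = 0, boxHigh = 1.2) {
  gpbbIterations <- as.integer(gpbbIterations)
  hqsPasses <- as.integer(hqsPasses)
  if (gpbbIterations < 1L) stop("'gpbbIterations' must be at least 1")
  if (hqsPasses < 1L) stop("'hqsPasses' must be at least 1")
  if (hqsGammaGrowth <= 1) stop("'hqsGammaGrowth' must exceed 1")
  if (boxLow >= boxHigh) stop("'boxLow' must be below 'boxHigh'")
  structure(list(gpbbIterations = gpbbIterations, hqsPasses = hqsPasses,
                 hqsGamma0 = hqsGamma0, hqsGammaGrowth = hqsGammaGrowth,
                 boxLow = boxLow, boxHigh = boxHigh), class = "SolverConfig")
}

#' Non-blind image restoration with bi-l0-l2 or l1 gradient regularization
#'
#' Minimizes `(alpha/2) ||f (*) k - g||^2 + R(f)` over the intensity box,
#' for a known kernel k. In `bi-l0-l2` mode the non-smooth l0 term is
#' split off: each pass first computes the auxiliary gradient field d by
#' group hard thresholding of `grad f` at `sqrt(2 betaF / (alpha gamma))`
#' (in the solver's fidelity-normalized scaling,
#' `sqrt(2 b / gamma)` with `b = betaF / alpha`), then runs GPBB on the
#' smooth quadratic
#' `1/2 ||f (*) k - g||^2 + (lambdaF betaF / alpha) ||grad f||^2 +
#' (gamma/2) ||grad f - d||^2`, with gamma growing geometrically. In `l1`
#' mode GPBB is applied directly to the Huber-smoothed anisotropic l1
#' gradient penalty (knee 1e-4 of the box dynamic range). Every GPBB step
#' projects exactly onto the box by clipping; the BB1 step length is
#' computed from the two most recent iterates (first step length 1) and
#' safeguarded to `[1e-8, 1e8]`. Each pass returns its best-energy
#' iterate, so whole-pass energies are non-increasing despite the
#' non-monotone BB steps. Deterministic given inputs.
#'
#' @param observed numeric matrix, the degraded image g.
#' @param k a [PSFKernel-class] (or feasible kernel matrix).
#' @param reg a [regularizationParams()].
#' @param cfg a [solverConfig()].
#' @return list with components `image` (the restored matrix) and `trace`
#'   (objective values per inner iteration, per-pass start/end energies,
#'   the gamma schedule, BB step sizes and the inner iteration count).
#' @export
restoreImage <- function(observed, k, reg = regularizationParams(),
                         cfg = solverConfig()) {
  stopifnot(inherits(reg, "RegularizationParams"),
            inherits(cfg, "SolverConfig"))
  assertImage(observed)
  w <- as_kernel_matrix(k)
  if (sum(abs(w)) == 0) stop("zero kernel rejected")
  if (nrow(w) > nrow(observed) || ncol(w) > ncol(observed))
    stop("kernel must not be larger than the image")
  # fidelity-normalized weights: the objective (alpha/2)||Kf-g||^2 +
  # betaF R(f) is scaled by 1/alpha so the data term has unit weight
  w0 <- reg$betaF / reg$alpha
  c2 <- reg$lambdaF * reg$betaF / reg$alpha
  gamma0 <- if (is.null(cfg$hqsGamma0)) 2 * w0 else cfg$hqsGamma0
  mode <- if (reg$mode == "bi-l0-l2") 0L else 1L
  huber_eps <- 1e-4 * (cfg$boxHigh - cfg$boxLow)
  P <- padded_dims(observed, nrow(w))
  res <- cpp_restore(observed, w, w0, w0, c2, mode,
                     cfg$gpbbIterations, cfg$hqsPasses, gamma0,
                     cfg$hqsGammaGrowth, cfg$boxLow, cfg$boxHigh,
                     huber_eps, P[1], P[2])
  list(image = res$image,
       trace = list(objective_values = as.numeric(res$objective_values),
                    pass_start = as.numeric(res$pass_start),
                    pass_end = as.numeric(res$pass_end),
                    gamma = as.numeric(res$gamma),
                    step_sizes = as.numeric(res$step_sizes),
                    inner_iterations_run = res$inner_iterations_run))
}
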