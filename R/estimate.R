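#' @include AllClasses.R AllGenerics.R eia.R refocus.R depth.R matting.R
NULL

#' Depth-estimation configuration
#'
#' Bundles every tunable of the depth pipeline with its default.  `alphaGrid
#' = NULL` falls back to [defaultAlphaGrid()] computed from the view stack.
#'
#' @param alphaGrid an [AlphaGrid-class], numeric vector, or `NULL`.
#' @param convention shear convention, see [shearOfAlpha()].
#' @param method refocusing method, `"shift_sum"` or `"fourier"`.
#' @param focusWindow odd focus-measure window (pixels).
#' @param tau reliability peak threshold (relative to the global median peak).
#' @param prominenceRatio reliability peak-to-mean ratio.
#' @param lambda data-precision weight of kept observations.
#' @param mattingRadius matting window radius.
#' @param mattingEpsilon matting covariance regulariser.
#' @param solveTol MAP residual tolerance.
#' @return a named list of settings.
#' @export
depthConfig <- function(alphaGrid = NULL,
                        convention = c("linear", "reciprocal"),
                        method = c("shift_sum", "fourier"),
                        focusWindow = 9L, tau = 1.0, prominenceRatio = 1.5,
                        lambda = 1e3, mattingRadius = 1L,
                        mattingEpsilon = 1e-5, solveTol = 1e-8) {
  list(alphaGrid = alphaGrid, convention = match.arg(convention),
       method = match.arg(method), focusWindow = as.integer(focusWindow),
       tau = tau, prominenceRatio = prominenceRatio, lambda = lambda,
       mattingRadius = as.integer(mattingRadius),
       mattingEpsilon = mattingEpsilon, solveTol = solveTol)
}

#' Estimate a relative depth map from an elemental image array
#'
#' The full depth chain: view extraction, focal-stack refocusing over the
#' alpha grid, Laplacian-energy focus measurement, argmax initial depth,
#' reliability filtering to sparse observations, matting Laplacian of the
#' central view, and the MAP linear solve.  Deterministic given its inputs;
#' stage failures are reported with the stage name.
#'
#' @param eia an [ElementalImageArray-class].
#' @param config a list from [depthConfig()].
#' @param full if `TRUE`, also return the intermediates.
#' @return a [RelativeDepthMap-class] at view resolution, or (with
#'   `full = TRUE`) a list with elements `depth`, `sparse`, `precision`,
#'   `initial`, `volume`, `stack`, `views`.
#' @export
estimateDepth <- function(eia, config = depthConfig(), full = FALSE) {
  views <- .stage("extract_views", extractViews(eia))
  stack <- .stage("build_focal_stack",
                  buildFocalStack(views, grid = config$alphaGrid,
                                  method = config$method,
                                  convention = config$convention))
  volume <- .stage("focus_measure", focusMeasure(stack, config$focusWindow))
  init <- .stage("initial_depth", initialDepth(volume))
  rf <- .stage("reliability_filter",
               reliabilityFilter(volume, init, tau = config$tau,
                                 lambda = config$lambda,
                                 prominenceRatio = config$prominenceRatio))
  L <- .stage("matting_laplacian",
              mattingLaplacian(centralView(views),
                               windowRadius = config$mattingRadius,
                               epsilon = config$mattingEpsilon))
  depth <- .stage("solve_map",
                  solveMap(L, rf$precision, rf$sparse, tol = config$solveTol))
  if (full)
    list(depth = depth, sparse = rf$sparse, precision = rf$precision,
         initial = init, volume = volume, stack = stack, views = views)
  else depth
}
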