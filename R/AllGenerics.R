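#' @include AllClasses.R
NULL

#' Accessors
#'
#' Small accessor generics for the light-field containers.
#'
#' @param x an object.
#' @param ... passed on to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("alphas", function(x) standardGeneric("alphas"))
#' @rdname accessors
#' @export
setGeneric("lensCount", function(x) standardGeneric("lensCount"))
#' @rdname accessors
#' @export
setGeneric("pixelsPerLens", function(x) standardGeneric("pixelsPerLens"))
#' @rdname accessors
#' @export
setGeneric("pixelArray", function(x) standardGeneric("pixelArray"))
#' @rdname accessors
#' @export
setGeneric("centralIndex", function(x) standardGeneric("centralIndex"))
#' @rdname accessors
#' @export
setGeneric("depthValues", function(x) standardGeneric("depthValues"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("laplacianMatrix", function(x) standardGeneric("laplacianMatrix"))
#' @rdname accessors
#' @export
setGeneric("cloudPoints", function(x) standardGeneric("cloudPoints"))
#' @rdname accessors
#' @export
setGeneric("rasterArray", function(x) standardGeneric("rasterArray"))
#' @rdname accessors
#' @export
setGeneric("rayCount", function(x) standardGeneric("rayCount"))

setMethod("alphas", "AlphaGrid", function(x) x@alphas)
setMethod("alphas", "FocalStack", function(x) x@alphaGrid@alphas)
setMethod("alphas", "FocusVolume", function(x) x@alphaGrid@alphas)
setMethod("lensCount", "LensArraySpec", function(x) c(x@lensCountU, x@lensCountV))
setMethod("lensCount", "ElementalImageArray", function(x) dim(x@pixels)[1:2])
setMethod("lensCount", "ViewStack", function(x) dim(x@views)[1:2])
setMethod("pixelsPerLens", "ElementalImageArray", function(x) x@pixelsPerLens)
setMethod("pixelsPerLens", "ViewStack", function(x) dim(x@views)[3:4])
setMethod("pixelArray", "ElementalImageArray", function(x) x@pixels)
setMethod("centralIndex", "ViewStack", function(x) x@centralIndex)
setMethod("depthValues", "RelativeDepthMap", function(x) x@depth)
setMethod("depthValues", "MetricDepthMap", function(x) x@depthMm)
setMethod("depthValues", "SparseDepth", function(x) x@values)
setMethod("validMask", "RelativeDepthMap", function(x) x@valid)
setMethod("validMask", "MetricDepthMap", function(x) x@valid)
setMethod("validMask", "SparseDepth", function(x) x@mask)
setMethod("laplacianMatrix", "MattingLaplacianMatrix", function(x) x@matrix)
setMethod("cloudPoints", "PointCloud", function(x) x@points)
setMethod("rasterArray", "RenderedEIA", function(x) x@raster)
setMethod("rayCount", "RenderedEIA", function(x) x@rayCount)

setMethod("show", "LensArraySpec", function(object) {
  cat(sprintf("LensArraySpec: %d x %d lenses, pitch %g mm, f %g mm, gap %g mm\n",
              object@lensCountU, object@lensCountV, object@lensPitch,
              object@focalLength, object@gap))
})

setMethod("show", "ElementalImageArray", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ElementalImageArray: %d x %d lenses, %d x %d px/lens (raster %d x %d)\n",
              d[1], d[2], d[3], d[4], d[1] * d[3], d[2] * d[4]))
})

setMethod("show", "ViewStack", function(object) {
  d <- dim(object@views)
  cat(sprintf("ViewStack: %d views of %d x %d px, central view (%d, %d) [1-based]\n",
              d[3] * d[4], d[1], d[2], object@centralIndex[1], object@centralIndex[2]))
})

setMethod("show", "FocalStack", function(object) {
  a <- object@alphaGrid@alphas
  d <- dim(object@images)
  cat(sprintf("FocalStack: %d images (%d x %d, %s), alpha %.4g..%.4g, %s/%s\n",
              d[4], d[1], d[2], if (d[3] == 1L) "luma" else "RGB",
              min(a), max(a), object@method, object@convention))
})

setMethod("show", "RelativeDepthMap", function(object) {
  cat(sprintf("RelativeDepthMap: %d x %d, alpha in [%.4g, %.4g], %.1f%% valid\n",
              nrow(object@depth), ncol(object@depth),
              min(object@depth[object@valid]), max(object@depth[object@valid]),
              100 * mean(object@valid)))
})

setMethod("show", "SparseDepth", function(object) {
  cat(sprintf("SparseDepth: %d x %d, %.1f%% observed\n",
              nrow(object@values), ncol(object@values), 100 * mean(object@mask)))
})

setMethod("show", "MattingLaplacianMatrix", function(object) {
  cat(sprintf("MattingLaplacianMatrix: %d x %d image (n = %d), r = %d, eps = %g\n",
              object@height, object@width, object@height * object@width,
              object@windowRadius, object@epsilon))
})

setMethod("show", "CalibrationFit", function(object) {
  cat(sprintf("CalibrationFit: mm = %.6g * alpha + %.6g  (r^2 = %.6f, n = %d)\n",
              object@slope, object@intercept, object@rSquared, object@nPoints))
})

setMethod("show", "MetricDepthMap", function(object) {
  v <- object@depthMm[object@valid]
  cat(sprintf("MetricDepthMap: %d x %d, depth %.4g..%.4g mm\n",
              nrow(object@depthMm), ncol(object@depthMm), min(v), max(v)))
})

setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud: %d points, lateral scale %g mm/px\n",
              nrow(object@points), object@lateralScale))
})

setMethod("show", "LayeredScene", function(object) {
  cat(sprintf("LayeredScene: %d layers, z %.4g..%.4g mm, %d occupied cells\n",
              length(object@zPlanes), min(object@zPlanes), max(object@zPlanes),
              sum(object@occupancy)))
})

setMethod("show", "RenderedEIA", function(object) {
  d <- dim(object@raster)
  cat(sprintf("RenderedEIA: %d x %d px (%d x %d lenses x %d x %d px), %g rays\n",
              d[1], d[2], object@lensCount[1], object@lensCount[2],
              object@pixelsPerLens[1], object@pixelsPerLens[2], object@rayCount))
})

setMethod("show", "Phantom", function(object) {
  cat(sprintf("Phantom: %d x %d, heights %.4g..%.4g mm, %g mm/px\n",
              nrow(object@heightMap), ncol(object@heightMap),
              min(object@heightMap), max(object@heightMap), object@lateralScale))
})
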