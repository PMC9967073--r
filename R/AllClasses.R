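#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal forceSymmetric rowSums norm solve t
NULL

.posLen <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0

#' Microlens / lens-array geometry
#'
#' Describes a lens array, either the capture-side microlens array (pitch in
#' micrometres converted to millimetres by the caller) or the display-side
#' lens sheet.  `gap` is the lens-to-sensor distance for capture and the
#' lens-to-panel spacer thickness for display.
#'
#' @slot lensCountU,lensCountV number of lenses along rows / columns.
#' @slot lensPitch centre-to-centre lens spacing (mm).
#' @slot focalLength lens focal length (mm).
#' @slot gap lens plane to sensor/panel distance (mm).
#' @exportClass LensArraySpec
setClass("LensArraySpec",
  slots = c(lensCountU = "integer", lensCountV = "integer",
            lensPitch = "numeric", focalLength = "numeric", gap = "numeric"),
  validity = function(object) {
    if (object@lensCountU < 1L || object@lensCountV < 1L)
      return("lens counts must be >= 1")
    for (s in c("lensPitch", "focalLength", "gap"))
      if (!.posLen(slot(object, s))) return(sprintf("%s must be a positive length", s))
    TRUE
  })

#' Constructor for [LensArraySpec-class]
#'
#' @param lensCountU,lensCountV lens counts (rows, columns).
#' @param lensPitch,focalLength,gap lengths in mm (see class doc).
#' @return a `LensArraySpec`.
#' @export
LensArraySpec <- function(lensCountU, lensCountV = lensCountU,
                          lensPitch = 0.125, focalLength = 2.4, gap = 2.4) {
  new("LensArraySpec", lensCountU = as.integer(lensCountU),
      lensCountV = as.integer(lensCountV), lensPitch = as.numeric(lensPitch),
      focalLength = as.numeric(focalLength), gap = as.numeric(gap))
}

#' Elemental image array (4D light field)
#'
#' The tiled raster behind the microlens array, stored as a 5D tensor indexed
#' `[u, v, s, t, channel]` where `(u, v)` is the lens (spatial sample) and
#' `(s, t)` the pixel within a lens (angular sample).  Intensities are
#' normalised to `[0, 1]`.
#'
#' @slot pixels 5D numeric array `(Nu, Nv, Ns, Nt, 3)`.
#' @slot layout the [LensArraySpec-class] the raster was captured through.
#' @slot pixelsPerLens integer pair `(Ns, Nt)`.
#' @exportClass ElementalImageArray
setClass("ElementalImageArray",
  slots = c(pixels = "array", layout = "LensArraySpec", pixelsPerLens = "integer"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 5L || d[5L] != 3L)
      return("pixels must be a (Nu, Nv, Ns, Nt, 3) array")
    if (!all(d[3:4] == object@pixelsPerLens))
      return("pixelsPerLens does not match tensor shape")
    if (d[1L] > object@layout@lensCountU || d[2L] > object@layout@lensCountV)
      return("more lens tiles than lenses in the layout")
    rng <- range(object@pixels)
    if (!all(is.finite(rng)) || rng[1L] < 0 || rng[2L] > 1 + 1e-12)
      return("intensities must be finite and in [0, 1]")
    TRUE
  })

#' Orthographic (sub-aperture) view stack
#'
#' View `(s, t)` is the `Nu x Nv` image formed by taking intra-lens pixel
#' `(s, t)` from every lens; the stack is stored with the same tensor layout
#' as the source [ElementalImageArray-class], so extraction is a pure
#' re-indexing.  `centralIndex` is the 1-based R index of the central view,
#' i.e. `floor(N/2) + 1` (the 0-based convention `floor(N/2)`; even counts
#' pick the upper-left of the central 2x2).
#'
#' @slot views 5D numeric array `(Nu, Nv, Ns, Nt, 3)`.
#' @slot centralIndex integer pair, 1-based `(s, t)` index of the central view.
#' @exportClass ViewStack
setClass("ViewStack",
  slots = c(views = "array", centralIndex = "integer"),
  validity = function(object) {
    d <- dim(object@views)
    if (length(d) != 5L || d[5L] != 3L)
      return("views must be a (Nu, Nv, Ns, Nt, 3) array")
    ci <- object@centralIndex
    if (length(ci) != 2L || any(ci < 1L) || ci[1L] > d[3L] || ci[2L] > d[4L])
      return("centralIndex outside the view grid")
    TRUE
  })

#' Refocus parameter grid
#'
#' Strictly increasing positive alpha values indexing virtual image planes;
#' alpha = 1 is the native (microlens) plane.  The native plane need not be a
#' member of the grid.
#'
#' @slot alphas numeric vector, strictly increasing, all > 0 (a length-1
#'   grid denotes a single refocus plane).
#' @exportClass AlphaGrid
setClass("AlphaGrid", slots = c(alphas = "numeric"),
  validity = function(object) {
    a <- object@alphas
    if (length(a) < 1L) return("need at least one alpha value")
    if (any(!is.finite(a)) || any(a <= 0)) return("alphas must be positive and finite")
    if (any(diff(a) <= 0)) return("alphas must be strictly increasing")
    TRUE
  })

#' @rdname AlphaGrid-class
#' @param alphas numeric vector of refocus parameters.
#' @export
AlphaGrid <- function(alphas) new("AlphaGrid", alphas = as.numeric(alphas))

#' Focal stack of digitally refocused images
#'
#' @slot images 4D array `(H, W, C, A)` with `C` 1 (luminance) or 3 (RGB) and
#'   one image per grid alpha.
#' @slot alphaGrid the [AlphaGrid-class] the stack was rendered over.
#' @slot convention shear convention, `"linear"` or `"reciprocal"`.
#' @slot method `"shift_sum"` or `"fourier"`.
#' @slot valid logical `(H, W, A)` array: pixels whose sample set was nonempty.
#' @exportClass FocalStack
setClass("FocalStack",
  slots = c(images = "array", alphaGrid = "AlphaGrid", convention = "character",
            method = "character", valid = "array"),
  validity = function(object) {
    d <- dim(object@images)
    if (length(d) != 4L || !(d[3L] %in% c(1L, 3L)))
      return("images must be (H, W, C, A) with C in {1, 3}")
    if (d[4L] != length(object@alphaGrid@alphas))
      return("image count must equal the number of grid alphas")
    if (!object@convention %in% c("linear", "reciprocal"))
      return("unknown shear convention")
    if (!identical(dim(object@valid), d[c(1L, 2L, 4L)]))
      return("valid mask shape must be (H, W, A)")
    TRUE
  })

#' Per-pixel, per-alpha focus measure volume
#'
#' @slot values nonnegative array `(H, W, A)` of Laplacian-energy focus scores.
#' @slot alphaGrid the grid of the source focal stack.
#' @exportClass FocusVolume
setClass("FocusVolume", slots = c(values = "array", alphaGrid = "AlphaGrid"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3L || d[3L] != length(object@alphaGrid@alphas))
      return("values must be (H, W, A) matching the alpha grid")
    if (any(object@values < 0)) return("focus measures must be nonnegative")
    TRUE
  })

#' Relative depth map in alpha units
#'
#' @slot depth numeric matrix of per-pixel alpha values.
#' @slot valid logical matrix, pixels carrying a depth estimate.
#' @slot alphaRange numeric pair, the grid span the depths live in.
#' @exportClass RelativeDepthMap
setClass("RelativeDepthMap",
  slots = c(depth = "matrix", valid = "matrix", alphaRange = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@depth), dim(object@valid)))
      return("depth and valid must have the same shape")
    if (length(object@alphaRange) != 2L || diff(object@alphaRange) <= 0)
      return("alphaRange must be an increasing pair")
    # MAP densification can over/undershoot the grid at depth discontinuities
    # (the colour-line prior is not an M-matrix); tolerate a bounded excess.
    v <- object@depth[object@valid]
    tol <- 0.25 * diff(object@alphaRange)
    if (length(v) && (any(!is.finite(v)) ||
        any(v < object@alphaRange[1L] - tol) || any(v > object@alphaRange[2L] + tol)))
      return("depth values outside the alpha range")
    TRUE
  })

#' Sparse high-confidence depth observations
#'
#' @slot values numeric matrix, alpha values on the mask, `NA` elsewhere.
#' @slot mask logical matrix of observed pixels.
#' @slot alphaRange numeric pair.
#' @exportClass SparseDepth
setClass("SparseDepth",
  slots = c(values = "matrix", mask = "matrix", alphaRange = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@values), dim(object@mask)))
      return("values and mask must have the same shape")
    frac <- mean(object@mask)
    if (frac <= 0) return("observed fraction must be positive")
    v <- object@values[object@mask]
    if (any(!is.finite(v)) || any(v < object@alphaRange[1L] - 1e-9) ||
        any(v > object@alphaRange[2L] + 1e-9))
      return("observed values outside the alpha range")
    TRUE
  })

#' Diagonal data precision for the MAP solve
#'
#' Zero exactly off the sparse-depth mask, a positive weight on it.
#'
#' @slot lambda nonnegative numeric matrix.
#' @exportClass PrecisionDiag
setClass("PrecisionDiag", slots = c(lambda = "matrix"),
  validity = function(object) {
    if (any(!is.finite(object@lambda)) || any(object@lambda < 0))
      return("precision entries must be finite and nonnegative")
    TRUE
  })

#' Matting Laplacian affinity matrix
#'
#' Sparse symmetric positive semidefinite matrix with zero row sums, built
#' from local colour-line models of the guiding image; pixel order is
#' column-major over the `height x width` grid.
#'
#' @slot matrix sparse symmetric `n x n` matrix (`Matrix::dsCMatrix`), n = H*W.
#' @slot height,width guiding-image shape.
#' @slot windowRadius local window radius r (windows are `(2r+1)^2` pixels).
#' @slot epsilon colour-covariance regulariser.
#' @exportClass MattingLaplacianMatrix
setClass("MattingLaplacianMatrix",
  slots = c(matrix = "Matrix", height = "integer", width = "integer",
            windowRadius = "integer", epsilon = "numeric"),
  validity = function(object) {
    n <- object@height * object@width
    if (!identical(dim(object@matrix), c(n, n)))
      return("matrix dimension must be (H*W) x (H*W)")
    if (object@windowRadius < 1L) return("windowRadius must be >= 1")
    if (object@epsilon <= 0) return("epsilon must be positive")
    TRUE
  })

#' Linear alpha-to-millimetre calibration fit
#'
#' @slot slope mm per alpha unit (the fitting coefficient).
#' @slot intercept mm.
#' @slot rSquared coefficient of determination, clamped to `[0, 1]`.
#' @slot nPoints number of calibration pairs used.
#' @exportClass CalibrationFit
setClass("CalibrationFit",
  slots = c(slope = "numeric", intercept = "numeric", rSquared = "numeric",
            nPoints = "integer"),
  validity = function(object) {
    if (object@nPoints < 2L) return("a line needs at least two points")
    if (!is.finite(object@rSquared) || object@rSquared < 0 || object@rSquared > 1)
      return("rSquared must be in [0, 1]")
    TRUE
  })

#' Metric depth map (millimetres)
#'
#' @slot depthMm numeric matrix of per-pixel depths in mm.
#' @slot fit the [CalibrationFit-class] used for the conversion (provenance).
#' @slot valid logical matrix.
#' @exportClass MetricDepthMap
setClass("MetricDepthMap",
  slots = c(depthMm = "matrix", fit = "CalibrationFit", valid = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@depthMm), dim(object@valid)))
      return("depthMm and valid must have the same shape")
    if (any(!is.finite(object@depthMm[object@valid])))
      return("depths must be finite where valid")
    TRUE
  })

#' ROI height measurement
#'
#' @slot roi integer `(x0, y0, x1, y1)`, 0-based half-open pixel rectangle.
#' @slot meanHeightMm mean height above the baseline inside the ROI.
#' @slot meanErrorMm mean absolute per-pixel error against the reference.
#' @slot referenceMm,baselineMm the stated reference height and baseline.
#' @slot nPixels ROI size.
#' @exportClass RoiMeasurement
setClass("RoiMeasurement",
  slots = c(roi = "integer", meanHeightMm = "numeric", meanErrorMm = "numeric",
            referenceMm = "numeric", baselineMm = "numeric", nPixels = "integer"))

#' RGB-D point cloud
#'
#' @slot points numeric matrix with columns `x, y, z` (mm) and `r, g, b` in
#'   `[0, 1]`, one row per retained pixel.
#' @slot lateralScale mm per source pixel.
#' @slot gridDim source raster shape `(H, W)` the cloud was lifted from.
#' @exportClass PointCloud
setClass("PointCloud",
  slots = c(points = "matrix", lateralScale = "numeric", gridDim = "integer"),
  validity = function(object) {
    p <- object@points
    if (ncol(p) != 6L) return("points must have columns x, y, z, r, g, b")
    if (nrow(p) && any(!is.finite(p))) return("coordinates must be finite")
    if (nrow(p) && (min(p[, 4:6]) < 0 || max(p[, 4:6]) > 1))
      return("colours must be in [0, 1]")
    TRUE
  })

#' Depth-layered scene for integral-imaging rendering
#'
#' @slot zPlanes strictly increasing layer depths (mm, scene units; larger z
#'   is taller, hence optically nearer the lens array when displayed).
#' @slot occupancy logical `(H, W, L)` array; each occupied lateral cell
#'   belongs to exactly one layer.
#' @slot colors numeric `(H, W, 3, L)` array of layer RGB.
#' @slot lateralScale mm per lateral cell.
#' @exportClass LayeredScene
setClass("LayeredScene",
  slots = c(zPlanes = "numeric", occupancy = "array", colors = "array",
            lateralScale = "numeric"),
  validity = function(object) {
    L <- length(object@zPlanes)
    if (L >= 2L && any(diff(object@zPlanes) <= 0))
      return("zPlanes must be strictly increasing")
    d <- dim(object@occupancy)
    if (length(d) != 3L || d[3L] != L)
      return("occupancy must be (H, W, L)")
    if (!identical(dim(object@colors), c(d[1L], d[2L], 3L, L)))
      return("colors must be (H, W, 3, L)")
    TRUE
  })

#' Integral-imaging display description
#'
#' @slot pixelPitch panel pixel pitch (mm).
#' @slot panelResolution integer pair, panel pixels (rows, cols).
#' @slot lensArray the display [LensArraySpec-class]; its `gap` is the
#'   lens-to-panel spacer (acrylic) thickness.
#' @exportClass DisplaySpec
setClass("DisplaySpec",
  slots = c(pixelPitch = "numeric", panelResolution = "integer",
            lensArray = "LensArraySpec"),
  validity = function(object) {
    if (!.posLen(object@pixelPitch)) return("pixelPitch must be positive")
    if (length(object@panelResolution) != 2L || any(object@panelResolution < 1L))
      return("panelResolution must be two positive integers")
    TRUE
  })

#' Display elemental image array rendered by direction-reversal calculation
#'
#' @slot raster numeric `(H, W, 3)` array in `[0, 1]`.
#' @slot lensCount,pixelsPerLens tiling: raster dims = lensCount * pixelsPerLens.
#' @slot rayCount number of rays cast (one per raster pixel by construction).
#' @slot background RGB fill for rays that hit no layer.
#' @exportClass RenderedEIA
setClass("RenderedEIA",
  slots = c(raster = "array", lensCount = "integer", pixelsPerLens = "integer",
            rayCount = "numeric", background = "numeric"),
  validity = function(object) {
    d <- dim(object@raster)
    if (length(d) != 3L || d[3L] != 3L) return("raster must be (H, W, 3)")
    if (!all(d[1:2] == object@lensCount * object@pixelsPerLens))
      return("raster dims must equal lensCount * pixelsPerLens")
    TRUE
  })

#' Ground-truth phantom for the capture simulator
#'
#' A textured height field standing in for the 3D-printed calibration and
#' test boards: a known height map (mm) with a high-contrast texture.
#'
#' @slot heightMap numeric matrix (mm).
#' @slot texture numeric `(H, W, 3)` array in `[0, 1]`.
#' @slot lateralScale mm per phantom cell.
#' @exportClass Phantom
setClass("Phantom",
  slots = c(heightMap = "matrix", texture = "array", lateralScale = "numeric"),
  validity = function(object) {
    if (any(!is.finite(object@heightMap))) return("heights must be finite")
    d <- dim(object@texture)
    if (length(d) != 3L || !all(d[1:2] == dim(object@heightMap)) || d[3L] != 3L)
      return("texture must be (H, W, 3) matching the height map")
    if (min(object@texture) < 0 || max(object@texture) > 1)
      return("texture must be in [0, 1]")
    TRUE
  })

#' Forward capture-simulation parameters
#'
#' `disparityGain` is the simulator's depth-to-parallax constant: the lateral
#' view shift, in view pixels per unit view-index offset, produced by 1 mm of
#' height above the native plane.  Its reciprocal is the mm-per-alpha slope a
#' distance calibration must recover under the linear shear convention.
#'
#' @slot lensCount integer pair `(Nu, Nv)`.
#' @slot pixelsPerLens integer pair `(Ns, Nt)` — the view-grid size.
#' @slot disparityGain view-pixels per view-index per mm.
#' @slot nativePlaneMm height imaged with zero parallax.
#' @slot noiseSigma additive Gaussian noise sd (0 disables).
#' @slot seed RNG seed for noise.
#' @exportClass CaptureConfig
setClass("CaptureConfig",
  slots = c(lensCount = "integer", pixelsPerLens = "integer",
            disparityGain = "numeric", nativePlaneMm = "numeric",
            noiseSigma = "numeric", seed = "integer"),
  validity = function(object) {
    if (any(object@lensCount < 1L) || any(object@pixelsPerLens < 1L))
      return("lens and pixel counts must be >= 1")
    if (!is.finite(object@disparityGain)) return("disparityGain must be finite")
    if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
    TRUE
  })

#' @rdname CaptureConfig-class
#' @param lensCount,pixelsPerLens integer pairs (scalars are recycled).
#' @param disparityGain,nativePlaneMm,noiseSigma,seed see class slots.
#' @export
CaptureConfig <- function(lensCount, pixelsPerLens, disparityGain = 1,
                          nativePlaneMm = 0, noiseSigma = 0, seed = 1L) {
  new("CaptureConfig", lensCount = rep(as.integer(lensCount), length.out = 2L),
      pixelsPerLens = rep(as.integer(pixelsPerLens), length.out = 2L),
      disparityGain = as.numeric(disparityGain),
      nativePlaneMm = as.numeric(nativePlaneMm),
      noiseSigma = as.numeric(noiseSigma), seed = as.integer(seed))
}
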