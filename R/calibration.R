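#' @include AllClasses.R AllGenerics.R
NULL

#' Fit the alpha-to-millimetre distance calibration
#'
#' Ordinary least-squares line `mm = slope * alpha + intercept` through the
#' calibration pairs (one representative alpha per stair floor against its
#' known height).  `intercept = FALSE` gives the strict single-coefficient
#' variant `mm = slope * alpha`; the default fits both, since a pure scale
#' cannot absorb the arbitrary origin of the alpha axis.
#'
#' @param alpha,mm numeric vectors of calibration pairs (or `alpha` a
#'   two-column matrix/data.frame of (alpha, mm)).
#' @param intercept fit an intercept (default `TRUE`).
#' @return a [CalibrationFit-class].
#' @export
fitDistanceCalibration <- function(alpha, mm = NULL, intercept = TRUE) {
  if (is.null(mm)) {
    alpha <- as.matrix(alpha)
    mm <- alpha[, 2L]; alpha <- alpha[, 1L]
  }
  if (length(alpha) != length(mm) || length(alpha) < 2L)
    stop("need at least two (alpha, mm) pairs")
  if (diff(range(alpha)) < .Machine$double.eps * max(1, abs(alpha[1L])))
    stop("degenerate calibration: all alpha values are equal")
  fit <- if (intercept) stats::lm(mm ~ alpha) else stats::lm(mm ~ alpha + 0)
  cf <- stats::coef(fit)
  slope <- unname(if (intercept) cf["alpha"] else cf[1L])
  icpt <- if (intercept) unname(cf["(Intercept)"]) else 0
  ssres <- sum(stats::residuals(fit)^2)
  sstot <- sum((mm - mean(mm))^2)
  r2 <- if (sstot > 0) max(0, min(1, 1 - ssres / sstot)) else 1
  new("CalibrationFit", slope = slope, intercept = icpt, rSquared = r2,
      nPoints = length(alpha))
}

.roiIndex <- function(roi, dims) {
  roi <- as.integer(roi)
  if (length(roi) != 4L) stop("roi must be (x0, y0, x1, y1)")
  x0 <- roi[1L]; y0 <- roi[2L]; x1 <- roi[3L]; y1 <- roi[4L]
  if (x1 <= x0 || y1 <= y0) stop("empty ROI")
  if (x0 < 0L || y0 < 0L || x1 > dims[2L] || y1 > dims[1L])
    stop(sprintf("ROI (%d,%d)-(%d,%d) outside the %d x %d map",
                 x0, y0, x1, y1, dims[2L], dims[1L]))
  list(rows = (y0 + 1L):y1, cols = (x0 + 1L):x1)
}

#' Representative depth of an ROI
#'
#' The trimmed mean over the central 80% of the ROI's values (10% shaved
#' from each tail), a robust stand-in for "a value close to the average"
#' that ignores salt outliers on the floor of a calibration stair.
#'
#' @param depth a [RelativeDepthMap-class] (or plain matrix).
#' @param roi integer `(x0, y0, x1, y1)`, 0-based half-open rectangle
#'   (`x` = column, `y` = row).
#' @param trim total fraction trimmed from each tail (default 0.1).
#' @return the representative alpha value.
#' @export
roiRepresentative <- function(depth, roi, trim = 0.1) {
  m <- if (is(depth, "RelativeDepthMap")) depth@depth else depth
  ix <- .roiIndex(roi, dim(m))
  mean(m[ix$rows, ix$cols], trim = trim)
}

#' Convert a relative depth map to millimetres
#'
#' Applies the calibration line per pixel: `depth_mm = slope * alpha +
#' intercept`.  Affine, hence order-preserving for positive slope.
#'
#' @param depth a [RelativeDepthMap-class].
#' @param fit a [CalibrationFit-class].
#' @return a [MetricDepthMap-class] carrying its fit as provenance.
#' @export
toMetric <- function(depth, fit) {
  new("MetricDepthMap", depthMm = fit@slope * depth@depth + fit@intercept,
      fit = fit, valid = depth@valid)
}

#' Measure an ROI of a metric depth map
#'
#' Mean height above the stated baseline plus the mean absolute per-pixel
#' error against a reference height — the per-board accuracy statistic used
#' on printed test boards of known height.
#'
#' @param metric a [MetricDepthMap-class].
#' @param roi 0-based half-open rectangle `(x0, y0, x1, y1)`.
#' @param referenceMm known true height of the feature (above baseline).
#' @param baselineMm depth of the base plane (default 0).
#' @return a [RoiMeasurement-class].
#' @export
measureRoi <- function(metric, roi, referenceMm, baselineMm = 0) {
  ix <- .roiIndex(roi, dim(metric@depthMm))
  h <- metric@depthMm[ix$rows, ix$cols] - baselineMm
  new("RoiMeasurement", roi = as.integer(roi),
      meanHeightMm = mean(h), meanErrorMm = mean(abs(h - referenceMm)),
      referenceMm = as.numeric(referenceMm),
      baselineMm = as.numeric(baselineMm), nPixels = length(h))
}

setMethod("show", "RoiMeasurement", function(object) {
  cat(sprintf(paste0("RoiMeasurement: mean height %.3f mm, mean |error| ",
                     "%.3f mm vs %.3f mm (%d px)\n"),
              object@meanHeightMm, object@meanErrorMm, object@referenceMm,
              object@nPixels))
})

#' Discrete entropy of an image
#'
#' Shannon entropy (bits) of the grey-level histogram after quantising to
#' `levels` bins.  By default the bins span the image's own min-max range
#' (depth maps are not natively 8-bit); `range = c(0, 255)` (or any pair)
#' pins them to an absolute scale for byte images.  A constant image has
#' zero entropy.
#'
#' @param image numeric matrix (an RGB array is scored on its luminance).
#' @param levels number of histogram bins (default 256).
#' @param range `NULL` for the data range, or a `(lo, hi)` pair.
#' @return entropy in bits, within `[0, log2(levels)]`.
#' @export
discreteEntropy <- function(image, levels = 256L, range = NULL) {
  levels <- as.integer(levels)
  if (levels < 2L) stop("need at least two levels")
  if (length(dim(image)) == 3L) image <- .luminance(image)
  v <- as.vector(image)
  if (any(!is.finite(v))) stop("image contains non-finite values")
  lo <- if (is.null(range)) min(v) else range[1L]
  hi <- if (is.null(range)) max(v) else range[2L]
  if (hi <= lo) return(0)
  bin <- pmin(pmax(floor((v - lo) / (hi - lo) * levels), 0), levels - 1L)
  p <- tabulate(bin + 1L, nbins = levels)
  p <- p[p > 0] / length(v)
  -sum(p * log2(p))
}
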