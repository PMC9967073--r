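#' @include AllClasses.R AllGenerics.R refocus.R
NULL

#' Laplacian-energy focus measure over a focal stack
#'
#' For every pixel and every stack alpha, the squared response of the 3x3
#' (4-neighbour) Laplacian is summed over a `window x window` neighbourhood
#' (reflect-padded borders).  RGB stacks are scored on their luminance.
#'
#' @param stack a [FocalStack-class].
#' @param window odd window side length (pixels), default 9.
#' @return a [FocusVolume-class].
#' @export
focusMeasure <- function(stack, window = 9L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("focus window must be an odd integer >= 3")
  r <- (window - 1L) %/% 2L
  d <- dim(stack@images)
  vals <- array(0, c(d[1L], d[2L], d[4L]))
  for (i in seq_len(d[4L])) {
    img <- if (d[3L] == 1L) stack@images[, , 1L, i] else
      .luminance(stack@images[, , , i])
    vals[, , i] <- .boxSum(.laplacian3(img)^2, r)
  }
  vals[vals < 0] <- 0  # guard fp round-off of the running sums
  new("FocusVolume", values = vals, alphaGrid = stack@alphaGrid)
}

#' Initial depth map by focus-measure argmax
#'
#' Per pixel, the grid alpha with the maximal focus value; ties break toward
#' the smallest alpha.
#'
#' @param volume a [FocusVolume-class].
#' @return a [RelativeDepthMap-class] (all pixels valid).
#' @export
initialDepth <- function(volume) {
  d <- dim(volume@values)
  m <- matrix(volume@values, d[1L] * d[2L], d[3L])
  idx <- max.col(m, ties.method = "first")
  a <- volume@alphaGrid@alphas
  new("RelativeDepthMap", depth = matrix(a[idx], d[1L], d[2L]),
      valid = matrix(TRUE, d[1L], d[2L]), alphaRange = range(a))
}

#' Reliability filtering to a sparse depth map
#'
#' Keeps only pixels whose focus peak is trustworthy: the peak value must
#' reach `tau` times the global median peak, and the peak must stand out
#' from the pixel's own focus profile by at least `prominenceRatio` times
#' its mean over alpha.  Kept pixels become sparse observations with data
#' precision `lambda`; all others get precision zero.
#'
#' @param volume a [FocusVolume-class].
#' @param initial the [RelativeDepthMap-class] from [initialDepth()].
#' @param tau peak threshold relative to the global median peak (default 1).
#' @param lambda positive precision weight for kept pixels (default 1e3).
#' @param prominenceRatio required peak-to-mean ratio (default 1.5).
#' @return list with `sparse` ([SparseDepth-class]) and `precision`
#'   ([PrecisionDiag-class]).
#' @export
reliabilityFilter <- function(volume, initial, tau = 1.0, lambda = 1e3,
                              prominenceRatio = 1.5) {
  if (tau <= 0 || lambda <= 0) stop("tau and lambda must be positive")
  d <- dim(volume@values)
  m <- matrix(volume@values, d[1L] * d[2L], d[3L])
  peak <- apply(m, 1L, max)
  avg <- rowMeans(m)
  keep <- peak >= tau * stats::median(peak) & peak >= prominenceRatio * avg
  if (!any(keep))
    stop("reliability filter removed every pixel; lower tau (or the ",
         "prominence ratio)")
  mask <- matrix(keep, d[1L], d[2L])
  vals <- ifelse(mask, initial@depth, NA_real_)
  lam <- matrix(0, d[1L], d[2L])
  lam[mask] <- lambda
  list(sparse = new("SparseDepth", values = vals, mask = mask,
                    alphaRange = range(volume@alphaGrid@alphas)),
       precision = new("PrecisionDiag", lambda = lam))
}
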