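#' @include AllClasses.R AllGenerics.R eia.R refocus.R calibration.R estimate.R
NULL

# Band-limited high-contrast random RGB texture: white noise box-smoothed a
# few times, then each channel stretched to full [0, 1] so the Laplacian
# focus measure has signal everywhere.
.randomTexture <- function(H, W, seed, smooth = 2L) {
  .withSeed(seed, {
    tex <- array(stats::runif(H * W * 3L), c(H, W, 3L))
    for (c in 1:3) {
      ch <- tex[, , c]
      for (k in seq_len(smooth)) ch <- .boxSum(ch, 1L) / 9
      rng <- range(ch)
      tex[, , c] <- if (diff(rng) > 0) (ch - rng[1L]) / diff(rng) else ch * 0 + 0.5
    }
    tex
  })
}

#' Staircase calibration phantom
#'
#' A step-shaped height field emulating the 3D-printed stair board used for
#' distance calibration: `nSteps` floors of width `stepWidthPx` at heights
#' `0, h, 2h, ...` (mm), textured with a seeded band-limited random pattern.
#'
#' @param nSteps number of floors (>= 2).
#' @param stepHeightMm floor-to-floor height (default 1 mm).
#' @param stepWidthPx floor width in phantom pixels.
#' @param textureSeed RNG seed for the texture (determinism contract).
#' @param heightPx phantom rows; default `nSteps * stepWidthPx` (square).
#' @param lateralScale mm per phantom pixel (default 0.1).
#' @return a [Phantom-class].
#' @export
makeStepPhantom <- function(nSteps, stepHeightMm = 1, stepWidthPx = 19L,
                            textureSeed = 1L, heightPx = NULL,
                            lateralScale = 0.1) {
  nSteps <- as.integer(nSteps)
  if (nSteps < 2L) stop("a staircase needs at least 2 floors")
  W <- nSteps * as.integer(stepWidthPx)
  H <- if (is.null(heightPx)) W else as.integer(heightPx)
  floorIdx <- (seq_len(W) - 1L) %/% as.integer(stepWidthPx)
  hm <- matrix(rep(floorIdx * stepHeightMm, each = H), H, W)
  new("Phantom", heightMap = hm, texture = .randomTexture(H, W, textureSeed),
      lateralScale = as.numeric(lateralScale))
}

#' Raised-shape measurement phantoms
#'
#' Binary-footprint columns on a flat base, emulating the printed test
#' boards: a triangular column, a cylinder, or a square column raised to
#' `heightMm`.  The square footprint is exactly `side^2` cells with
#' `side = floor(sizePx / 2)`.
#'
#' @param shape `"triangular_column"`, `"cylinder"` or `"square_column"`.
#' @param heightMm column height (mm, >= 0).
#' @param textureSeed RNG seed for the texture.
#' @param sizePx phantom side length (default 76).
#' @param lateralScale mm per phantom pixel.
#' @return a [Phantom-class].
#' @export
makeShapePhantom <- function(shape = c("triangular_column", "cylinder",
                                       "square_column"),
                             heightMm, textureSeed = 1L, sizePx = 76L,
                             lateralScale = 0.1) {
  shape <- match.arg(shape)
  if (heightMm < 0) stop("heightMm must be >= 0")
  n <- as.integer(sizePx)
  ctr <- (n + 1) / 2
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  foot <- switch(shape,
    cylinder = (rows - ctr)^2 + (cols - ctr)^2 <= (n / 4)^2,
    square_column = {
      side <- n %/% 2L
      r0 <- (n - side) %/% 2L
      rows > r0 & rows <= r0 + side & cols > r0 & cols <= r0 + side
    },
    triangular_column = {
      # upright isoceles triangle inscribed in the central half
      h <- n / 2
      top <- ctr - h / 2
      inY <- rows >= top & rows <= top + h
      halfw <- (rows - top) / 2
      inY & abs(cols - ctr) <= halfw
    })
  hm <- matrix(0, n, n)
  hm[foot] <- heightMm
  new("Phantom", heightMap = hm, texture = .randomTexture(n, n, textureSeed),
      lateralScale = as.numeric(lateralScale))
}

#' Simulate a pinhole-array light-field capture of a phantom
#'
#' Occlusion-free Lambertian height-field model with depth-proportional
#' parallax: view `(s, t)` sees the texture shifted by
#' `-gamma * (height - nativePlane) * ((s, t) - central view index)`
#' (bilinear sampling, shifts clamped at the grid edge with a warning), so a
#' plane at height `z` comes into focus at shear `beta = gamma * (z - z0)` —
#' exactly linear in depth.  Views are assembled into the elemental image
#' array layout; optional i.i.d. Gaussian noise (clipped to `[0, 1]`) is
#' drawn from the config seed, making the capture deterministic.
#'
#' The phantom's lateral grid must match the lens count (one texture sample
#' per lens).
#'
#' @param phantom a [Phantom-class].
#' @param cfg a [CaptureConfig-class].
#' @return an [ElementalImageArray-class].
#' @export
simulateCapture <- function(phantom, cfg) {
  d <- dim(phantom@heightMap)
  if (!all(d == cfg@lensCount))
    stop(sprintf("phantom grid %d x %d must match the %d x %d lens count",
                 d[1L], d[2L], cfg@lensCount[1L], cfg@lensCount[2L]))
  Nu <- d[1L]; Nv <- d[2L]
  Ns <- cfg@pixelsPerLens[1L]; Nt <- cfg@pixelsPerLens[2L]
  ci <- c(Ns %/% 2L + 1L, Nt %/% 2L + 1L)
  dz <- phantom@heightMap - cfg@nativePlaneMm
  rows <- matrix(seq_len(Nu), Nu, Nv)
  cols <- matrix(seq_len(Nv), Nu, Nv, byrow = TRUE)
  pixels <- array(0, c(Nu, Nv, Ns, Nt, 3L))
  clamped <- FALSE
  for (s in seq_len(Ns)) for (t in seq_len(Nt)) {
    ys <- rows - cfg@disparityGain * dz * (s - ci[1L])
    xs <- cols - cfg@disparityGain * dz * (t - ci[2L])
    for (c in 1:3) {
      sm <- .sampleBilinear(phantom@texture[, , c], as.vector(ys),
                            as.vector(xs))
      clamped <- clamped || sm$clamped
      pixels[, , s, t, c] <- matrix(sm$values, Nu, Nv)
    }
  }
  if (clamped)
    warning("parallax shifts exceeded the phantom grid and were clamped")
  if (cfg@noiseSigma > 0) {
    pixels <- .withSeed(cfg@seed,
      .clip01(pixels + stats::rnorm(length(pixels), sd = cfg@noiseSigma)))
  }
  layout <- LensArraySpec(Nu, Nv)
  new("ElementalImageArray", pixels = pixels, layout = layout,
      pixelsPerLens = c(Ns, Nt))
}

#' Packaged end-to-end test fixtures
#'
#' A named phantom, its simulated capture, the exact alpha-to-mm calibration
#' line implied by the simulator's linear parallax model under the linear
#' shear convention (`alpha* = 1 + gamma (z - z0)`, hence
#' `mm = alpha / gamma + (z0 - 1/gamma)`), the ground-truth metric depth
#' map, and a depth-estimation config whose alpha grid brackets the
#' fixture's depth range.
#'
#' Fixtures: `"steps4"` (4-floor staircase, 1 mm floors), `"flat"`
#' (zero-variance plane at 1.5 mm), `"cylinder2mm"`, `"triangle1mm"`,
#' `"square3mm"`.
#'
#' @param name fixture name.
#' @param seed texture/noise seed.
#' @param lenses lens count per side (default 76).
#' @param viewsPerSide intra-lens pixels per side (default 9).
#' @param noiseSigma additive noise sd (default 0, the calibration-grade
#'   setting).
#' @return list with `eia`, `phantom`, `truth` ([MetricDepthMap-class]),
#'   `fit` (the true [CalibrationFit-class]), `cfg`, `config`.
#' @export
endToEndFixture <- function(name = c("steps4", "flat", "cylinder2mm",
                                     "triangle1mm", "square3mm"),
                            seed = 1L, lenses = 76L, viewsPerSide = 9L,
                            noiseSigma = 0) {
  name <- match.arg(name)
  lenses <- as.integer(lenses)
  gamma <- 0.5   # view-px per view-index per mm
  z0 <- 1.5      # native plane mid-stair: bounds the parallax shifts
  phantom <- switch(name,
    steps4 = makeStepPhantom(4L, stepHeightMm = 1,
                             stepWidthPx = lenses %/% 4L,
                             textureSeed = seed, heightPx = lenses),
    flat = {
      p <- makeStepPhantom(2L, stepHeightMm = 0,
                           stepWidthPx = lenses %/% 2L,
                           textureSeed = seed, heightPx = lenses)
      p@heightMap[] <- 1.5
      p
    },
    cylinder2mm = makeShapePhantom("cylinder", 2, textureSeed = seed,
                                   sizePx = lenses),
    triangle1mm = makeShapePhantom("triangular_column", 1,
                                   textureSeed = seed, sizePx = lenses),
    square3mm = makeShapePhantom("square_column", 3, textureSeed = seed,
                                 sizePx = lenses))
  if (ncol(phantom@heightMap) != lenses)  # guard non-divisible floor widths
    phantom@heightMap <- phantom@heightMap[, seq_len(lenses)]
  cfg <- CaptureConfig(lensCount = dim(phantom@heightMap),
                       pixelsPerLens = viewsPerSide, disparityGain = gamma,
                       nativePlaneMm = z0, noiseSigma = noiseSigma,
                       seed = seed)
  eia <- suppressWarnings(simulateCapture(phantom, cfg))
  fit <- new("CalibrationFit", slope = 1 / gamma,
             intercept = z0 - 1 / gamma, rSquared = 1, nPoints = 2L)
  truth <- new("MetricDepthMap", depthMm = phantom@heightMap, fit = fit,
               valid = matrix(TRUE, nrow(phantom@heightMap),
                              ncol(phantom@heightMap)))
  zr <- range(phantom@heightMap)
  margin <- max(0.2, 0.1 * gamma * diff(zr))
  grid <- AlphaGrid(seq(1 + gamma * (zr[1L] - z0) - margin,
                        1 + gamma * (zr[2L] - z0) + margin,
                        length.out = 64L))
  list(eia = eia, phantom = phantom, truth = truth, fit = fit, cfg = cfg,
       config = depthConfig(alphaGrid = grid))
}
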