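mkMetric <- function(m) {
  fit <- new("CalibrationFit", slope = 1, intercept = 0, rSquared = 1,
             nPoints = 2L)
  new("MetricDepthMap", depthMm = m, fit = fit,
      valid = matrix(TRUE, nrow(m), ncol(m)))
}

test_that("depth upsampling is exact on ramps and bounded by the input", {
  ramp <- mkMetric(outer(seq(0, 1, length.out = 9), rep(1, 7)))
  up <- upsampleDepth(ramp, c(17L, 13L))
  want <- outer(seq(0, 1, length.out = 17), rep(1, 13))
  expect_equal(depthValues(up), want, tolerance = 1e-6)

  cst <- mkMetric(matrix(3.2, 5, 5))
  expect_true(all(depthValues(upsampleDepth(cst, c(31L, 31L))) == 3.2))

  expect_identical(upsampleDepth(ramp, c(9L, 7L)), ramp)  # identity size
  expect_error(upsampleDepth(ramp, c(5L, 7L)), "downsampling")

  set.seed(21)
  rough <- mkMetric(matrix(runif(64), 8, 8))
  upr <- depthValues(upsampleDepth(rough, c(23L, 23L)))
  expect_gte(min(upr), min(depthValues(rough)))
  expect_lte(max(upr), max(depthValues(rough)))
})

test_that("Coons patches restore planar holes exactly", {
  plane <- outer(seq_len(12), seq_len(12),
                 function(y, x) 0.3 * y - 0.2 * x + 1)
  holes <- matrix(FALSE, 12, 12)
  holes[4:7, 5:9] <- TRUE
  broken <- plane; broken[holes] <- -99
  fixed <- fillHoles(mkMetric(broken), holes)
  expect_equal(depthValues(fixed), plane, tolerance = 1e-12)
  # non-hole pixels untouched even in the broken map
  partial <- fillHoles(mkMetric(broken * 1), holes)
  expect_identical(depthValues(partial)[!holes], plane[!holes])
  # no holes -> identity
  expect_identical(depthValues(fillHoles(mkMetric(plane),
                                         matrix(FALSE, 12, 12))), plane)
})

test_that("Coons patches beat constant fill on curved surfaces", {
  quadr <- outer(seq_len(14), seq_len(14),
                 function(y, x) 0.02 * (y - 7)^2 + 0.015 * (x - 7)^2)
  holes <- matrix(FALSE, 14, 14)
  holes[5:9, 6:10] <- TRUE
  broken <- quadr; broken[holes] <- 0
  fixed <- depthValues(fillHoles(mkMetric(broken), holes))
  coonsErr <- max(abs(fixed[holes] - quadr[holes]))
  constErr <- max(abs(mean(quadr[!holes]) - quadr[holes]))
  expect_lt(coonsErr, constErr)
})

test_that("border holes fall back to nearest-valid extension with a warning", {
  m <- matrix(2, 8, 8)
  holes <- matrix(FALSE, 8, 8)
  holes[1:2, 3:5] <- TRUE
  broken <- m; broken[holes] <- -1
  expect_warning(fixed <- fillHoles(mkMetric(broken), holes), "border")
  expect_equal(depthValues(fixed), m, tolerance = 1e-12)
})

test_that("point clouds conserve retained pixels and geometry", {
  set.seed(22)
  d <- mkMetric(matrix(runif(100, 1, 2), 10, 10))
  rgb <- array(runif(300), c(10, 10, 3))
  pc <- buildPointCloud(d, rgb, lateralScale = 0.5)
  expect_identical(nrow(cloudPoints(pc)), 100L)
  # x = col * scale, y = row * scale (0-based), z = depth
  p <- cloudPoints(pc)
  i <- which(p[, "x"] == 0.5 * 3 & p[, "y"] == 0.5 * 2)
  expect_identical(unname(p[i, "z"]), depthValues(d)[3, 4])
  expect_identical(unname(p[i, c("r", "g", "b")]),
                   c(rgb[3, 4, 1], rgb[3, 4, 2], rgb[3, 4, 3]))
  flat <- buildPointCloud(mkMetric(matrix(1.5, 4, 4)), rgb[1:4, 1:4, ], 1)
  expect_true(all(cloudPoints(flat)[, "z"] == 1.5))
  expect_identical(nrow(cloudPoints(buildPointCloud(d, rgb, 0.5,
                                                    stride = 2L))), 25L)
  expect_error(buildPointCloud(d, rgb[1:5, , ], 1), "resolutions differ")
})

test_that("layering partitions points into uniform z bins", {
  set.seed(23)
  d <- mkMetric(matrix(runif(36, 0, 3), 6, 6))
  pc <- buildPointCloud(d, array(0.5, c(6, 6, 3)), 1)
  sc <- layerScene(pc, 4L)
  expect_length(sc@zPlanes, 4L)
  expect_identical(sum(sc@occupancy), 36L)                # every point placed
  expect_true(all(apply(sc@occupancy, c(1, 2), sum) == 1L))  # exactly once
  # one layer keeps everything together
  expect_identical(sum(layerScene(pc, 1L)@occupancy), 36L)
  # two distinct z values split perfectly into two layers
  d2 <- mkMetric(matrix(rep(c(1, 2), 18), 6, 6))
  sc2 <- layerScene(buildPointCloud(d2, array(0.5, c(6, 6, 3)), 1), 2L)
  expect_identical(as.vector(table(sc2@occupancy[, , 1L])), c(18L, 18L))
  # degenerate range collapses to a single layer
  sc3 <- layerScene(buildPointCloud(mkMetric(matrix(1, 3, 3)),
                                    array(0.1, c(3, 3, 3)), 1), 5L)
  expect_length(sc3@zPlanes, 1L)
})

test_that("interaction transforms are rigid up to uniform scale", {
  set.seed(24)
  d <- mkMetric(matrix(runif(25, 0, 2), 5, 5))
  pc <- buildPointCloud(d, array(runif(75), c(5, 5, 3)), 0.7)
  expect_equal(cloudPoints(applyInteraction(pc, c(0, 0, 0), 1)),
               cloudPoints(pc), tolerance = 1e-12)
  z2 <- applyInteraction(pc, c(0, 0, 0), 2)
  p0 <- cloudPoints(pc); p2 <- cloudPoints(z2)
  expect_identical(nrow(p2), nrow(p0))
  d0 <- sqrt(sum((p0[1, 1:3] - p0[10, 1:3])^2))
  d2 <- sqrt(sum((p2[1, 1:3] - p2[10, 1:3])^2))
  expect_equal(d2, 2 * d0, tolerance = 1e-9)
  full <- applyInteraction(pc, c(0, 360, 0), 1)
  expect_equal(cloudPoints(full), cloudPoints(pc), tolerance = 1e-9)
  rot <- applyInteraction(pc, c(30, -20, 45), 1.3)
  dr <- sqrt(sum((cloudPoints(rot)[1, 1:3] - cloudPoints(rot)[10, 1:3])^2))
  expect_equal(dr, 1.3 * d0, tolerance = 1e-9)  # distance ratios preserved
  expect_error(applyInteraction(pc, zoom = 0), "positive")
})

smallDisplay <- function(NL = 8L)
  DisplaySpec(pixelPitch = 0.2, panelResolution = c(NL * 5L, NL * 5L),
              lensArray = LensArraySpec(NL, NL, lensPitch = 1,
                                        focalLength = 3.3, gap = 6))

test_that("an empty scene renders pure background", {
  sc <- randomScene(5L, 5L, 2L, seed = 30L, fill = 0)
  eia <- renderEIADRC(sc, smallDisplay(4L), eiaPixelsPerLens = 5L,
                      background = c(0.1, 0.2, 0.3), lensCount = 4L)
  r <- rasterArray(eia)
  expect_true(all(r[, , 1] == 0.1) && all(r[, , 2] == 0.2) &&
                all(r[, , 3] == 0.3))
  expect_identical(rayCount(eia), 4 * 4 * 5 * 5)
})

test_that("DRC equals the brute-force z-buffer oracle exactly", {
  disp <- smallDisplay(8L)
  for (sd in 1:4) {
    sc <- randomScene(10L, 10L, 3L, seed = sd, fill = 0.7,
                      overlap = sd %% 2L == 0L, lateralScale = 0.6,
                      zPlanes = c(0, 0.9, 2.1))
    eia <- renderEIADRC(sc, disp, eiaPixelsPerLens = 5L, lensCount = 8L,
                        background = c(0, 0, 0))
    orc <- zbufferOracle(sc, disp, 8L, 5L, background = c(0, 0, 0))
    expect_identical(rasterArray(eia), orc$raster)
    expect_identical(rayCount(eia), 8 * 8 * 5 * 5)  # one ray per EIA pixel
  }
})

test_that("occlusion is monotone: nearer layers never disturb yet-nearer hits", {
  disp <- smallDisplay(6L)
  base <- randomScene(8L, 8L, 3L, seed = 9L, fill = 0.6, overlap = TRUE,
                      zPlanes = c(0, 1, 2))
  # add a new nearest layer (largest z = optically nearest)
  withNew <- base
  set.seed(99)
  newOcc <- matrix(runif(64) < 0.5, 8, 8)
  withNew@zPlanes <- c(base@zPlanes, 2.6)
  occ <- array(FALSE, c(8, 8, 4)); occ[, , 1:3] <- base@occupancy
  occ[, , 4] <- newOcc
  col <- array(0, c(8, 8, 3, 4)); col[, , , 1:3] <- base@colors
  col[, , , 4] <- array(runif(192), c(8, 8, 3))
  withNew@occupancy <- occ; withNew@colors <- col

  rBase <- rasterArray(renderEIADRC(base, disp, 5L, lensCount = 6L))
  rNew <- rasterArray(renderEIADRC(withNew, disp, 5L, lensCount = 6L))
  # oracle tells which layer each ray struck in the base scene; rays whose
  # base hit is strictly nearer than the inserted layer must be unchanged
  orc <- zbufferOracle(base, disp, 6L, 5L)
  geoB <- drcGeometry(base, disp, 6L, 5L)
  geoN <- drcGeometry(withNew, disp, 6L, 5L)
  Dnew <- geoN$D[4L]
  protected <- orc$hitLayer > 0L
  protected[protected] <- geoB$D[orc$hitLayer[protected]] < Dnew
  for (ch in 1:3)
    expect_identical(rNew[, , ch][protected], rBase[, , ch][protected])
})

test_that("preview views select the reverse-pinhole pixel per lens", {
  # single-layer scene: the 0 degree view reproduces the layer's occupancy
  # pattern at lens resolution
  H <- 6L
  occ <- array(FALSE, c(H, H, 1L))
  set.seed(31)
  occ[, , 1L] <- matrix(runif(H * H) < 0.5, H, H)
  colr <- array(runif(H * H * 3L), c(H, H, 3L, 1L))
  # lateralScale = lens pitch makes the lens-to-cell mapping the identity
  sc <- new("LayeredScene", zPlanes = 1, occupancy = occ, colors = colr,
            lateralScale = 1)
  disp <- smallDisplay(H)
  eia <- renderEIADRC(sc, disp, 5L, lensCount = H, background = c(0, 0, 0))
  v0 <- previewViews(eia, disp, 0)[[1L]]
  for (ch in 1:3) {
    want <- colr[, , ch, 1L]
    want[!occ[, , 1L]] <- 0
    expect_identical(v0[, , ch], want)
  }
  # symmetric scene: +/- theta views mirror
  a1 <- colr[, , , 1L]
  occM <- occ; occM[, , 1L] <- occ[, H:1, 1L] | occ[, , 1L]
  colM <- colr; colM[, , , 1L] <- (a1 + a1[, H:1, ]) / 2
  scM <- new("LayeredScene", zPlanes = 1, occupancy = occM, colors = colM,
             lateralScale = 1)
  eiaM <- renderEIADRC(scM, disp, 5L, lensCount = H, background = c(0, 0, 0))
  vp <- previewViews(eiaM, disp, cbind(0, 1.5))[[1L]]
  vm <- previewViews(eiaM, disp, cbind(0, -1.5))[[1L]]
  expect_equal(vp, vm[, H:1, ], tolerance = 1e-12)
  # empty scene previews are background
  e0 <- renderEIADRC(randomScene(4L, 4L, 1L, fill = 0), disp, 5L,
                     lensCount = H, background = c(0.2, 0.2, 0.2))
  ve <- previewViews(e0, disp, 0, background = c(0.2, 0.2, 0.2))[[1L]]
  expect_true(all(ve == 0.2))
  # angle beyond the lens acceptance warns
  expect_warning(previewViews(eia, disp, 45), "acceptance")
})

test_that("PLY round-trips in both encodings", {
  set.seed(25)
  d <- mkMetric(matrix(runif(16, 0, 2), 4, 4))
  pc <- buildPointCloud(d, array(runif(48), c(4, 4, 3)), 0.25)
  for (fmt in c("ascii", "binary_little_endian")) {
    f <- tempfile(fileext = ".ply")
    writePLY(pc, f, fmt)
    back <- readPLY(f)
    expect_equal(cloudPoints(back)[, 1:3], cloudPoints(pc)[, 1:3],
                 tolerance = 1e-6)  # float32 precision
    expect_equal(cloudPoints(back)[, 4:6], cloudPoints(pc)[, 4:6],
                 tolerance = 1 / 255)
    expect_identical(back@gridDim, pc@gridDim)
    expect_equal(back@lateralScale, pc@lateralScale, tolerance = 1e-15)
  }
})
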