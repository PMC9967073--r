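mkStack <- function(imgs, alphas) {
  H <- nrow(imgs[[1L]]); W <- ncol(imgs[[1L]])
  a <- array(0, c(H, W, 1L, length(imgs)))
  for (i in seq_along(imgs)) a[, , 1L, i] <- imgs[[i]]
  new("FocalStack", images = a, alphaGrid = AlphaGrid(alphas),
      convention = "linear", method = "shift_sum",
      valid = array(TRUE, c(H, W, length(imgs))))
}

test_that("focus measure is Laplacian energy summed over the window", {
  set.seed(1)
  # constant slice scores exactly zero
  st <- mkStack(list(matrix(0.6, 8, 8), matrix(runif(64), 8, 8)), c(1, 1.2))
  fv <- focusMeasure(st, window = 3L)
  expect_identical(fv@values[, , 1L], matrix(0, 8, 8))
  expect_true(all(fv@values >= 0))
  expect_error(focusMeasure(st, window = 4L), "odd")
})

test_that("focus measure matches a brute-force convolution oracle", {
  set.seed(42)
  img <- matrix(runif(49), 7, 7)
  st <- mkStack(list(img, img * 0 + 0.2), c(1, 1.5))
  fv <- focusMeasure(st, window = 3L)
  # oracle: reflect-pad, 3x3 Laplacian, square, sum over 3x3 neighbourhood
  pad <- function(m, r) {
    H <- nrow(m); W <- ncol(m)
    ri <- c(pmin(r:1, H), 1:H, H - pmin(1:r, H) + 1L)
    ci <- c(pmin(r:1, W), 1:W, W - pmin(1:r, W) + 1L)
    m[ri, ci]
  }
  p <- pad(img, 1L)
  lap <- matrix(0, 7, 7)
  for (y in 1:7) for (x in 1:7)
    lap[y, x] <- p[y, x + 1] + p[y + 2, x + 1] + p[y + 1, x] +
      p[y + 1, x + 2] - 4 * img[y, x]
  e <- lap^2
  pe <- pad(e, 1L)
  want <- matrix(0, 7, 7)
  for (y in 1:7) for (x in 1:7)
    want[y, x] <- sum(pe[y:(y + 2), x:(x + 2)])
  expect_equal(fv@values[, , 1L], want, tolerance = 1e-12)
})

test_that("in-focus alpha wins the argmax on a textured plane", {
  h <- 2.2  # mm; native plane at 1.5, gamma 1 -> alpha* = 1.7
  ph <- makeStepPhantom(2L, stepHeightMm = 0, stepWidthPx = 16L,
                        textureSeed = 5L)
  ph@heightMap[] <- h
  cfg <- CaptureConfig(lensCount = 32L, pixelsPerLens = 7L,
                       disparityGain = 1, nativePlaneMm = 1.5)
  eia <- suppressWarnings(simulateCapture(ph, cfg))
  grid <- seq(1.2, 2.2, by = 0.1)  # contains alpha* = 1.7
  st <- buildFocalStack(extractViews(eia), grid)
  fv <- focusMeasure(st)
  init <- initialDepth(fv)
  core <- depthValues(init)[6:27, 6:27]
  expect_gte(mean(abs(core - 1.7) < 1e-9), 0.95)
})

test_that("initial depth is the per-pixel argmax with min-alpha ties", {
  set.seed(9)
  vals <- array(runif(6 * 5 * 4), c(6, 5, 4))
  fv <- new("FocusVolume", values = vals, alphaGrid = AlphaGrid(c(1, 2, 3, 4)))
  d <- depthValues(initialDepth(fv))
  for (y in 1:6) for (x in 1:5)
    expect_identical(d[y, x], c(1, 2, 3, 4)[which.max(vals[y, x, ])])
  # all-equal profile -> smallest alpha everywhere
  fv2 <- new("FocusVolume", values = array(0.5, c(3, 3, 4)),
             alphaGrid = AlphaGrid(c(1.1, 2, 3, 4)))
  expect_identical(depthValues(initialDepth(fv2)), matrix(1.1, 3, 3))
})

test_that("reliability filter keeps everything in the no-op limit", {
  set.seed(2)
  vals <- array(runif(5 * 5 * 3, 0.1, 1), c(5, 5, 3))
  fv <- new("FocusVolume", values = vals, alphaGrid = AlphaGrid(c(1, 2, 3)))
  init <- initialDepth(fv)
  rf <- reliabilityFilter(fv, init, tau = 1e-9, lambda = 7,
                          prominenceRatio = 1)
  expect_true(all(validMask(rf$sparse)))
  expect_identical(rf$precision@lambda, matrix(7, 5, 5))
  expect_error(reliabilityFilter(fv, init, tau = 1e9), "lower tau")
})

test_that("reliability filter prefers textured over flat regions", {
  # left half flat texture (no focus signal), right half random
  ph <- makeStepPhantom(2L, stepHeightMm = 0, stepWidthPx = 16L,
                        textureSeed = 3L)
  ph@heightMap[] <- 2.0
  ph@texture[, 1:16, ] <- 0.5
  cfg <- CaptureConfig(lensCount = 32L, pixelsPerLens = 7L,
                       disparityGain = 1, nativePlaneMm = 1.5)
  eia <- suppressWarnings(simulateCapture(ph, cfg))
  st <- buildFocalStack(extractViews(eia), seq(1.0, 2.0, by = 0.1))
  fv <- focusMeasure(st)
  rf <- reliabilityFilter(fv, initialDepth(fv))
  kept <- which(validMask(rf$sparse), arr.ind = TRUE)
  # membership precision: kept pixels lie in the textured half
  expect_gte(mean(kept[, 2L] >= 16L), 0.9)
})

test_that("matting Laplacian matches the naive per-window oracle", {
  set.seed(11)
  img <- array(runif(4 * 4 * 3), c(4, 4, 3))
  L <- mattingLaplacian(img, windowRadius = 1L, epsilon = 1e-5)
  dense <- denseMattingOracle(img, 1L, 1e-5)
  expect_lt(max(abs(as.matrix(laplacianMatrix(L)) - dense)), 1e-10)
})

test_that("matting Laplacian satisfies its structural invariants", {
  set.seed(12)
  for (k in 1:3) {
    img <- array(runif(8 * 8 * 3), c(8, 8, 3))
    L <- laplacianMatrix(mattingLaplacian(img))
    expect_identical(max(abs(L - Matrix::t(L))), 0)        # exact symmetry
    expect_lt(max(abs(Matrix::rowSums(L))), 1e-9)          # L 1 = 0
    ev <- eigen(as.matrix(L), symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)                             # PSD
  }
  expect_error(mattingLaplacian(array(c(NA, runif(26)), c(3, 3, 3))),
               "non-finite")
})

mkObs <- function(vals, mask, lambda, range = c(0, 10)) {
  v <- vals; v[!mask] <- NA_real_
  lam <- matrix(0, nrow(vals), ncol(vals)); lam[mask] <- lambda
  list(sparse = new("SparseDepth", values = v, mask = mask,
                    alphaRange = range),
       precision = new("PrecisionDiag", lambda = lam))
}

test_that("MAP solve returns the observations when the data term dominates", {
  set.seed(13)
  img <- array(runif(6 * 6 * 3), c(6, 6, 3))
  L <- mattingLaplacian(img)
  vals <- matrix(runif(36, 1, 9), 6, 6)
  mask <- matrix(TRUE, 6, 6)
  lam <- 1e6 * max(abs(laplacianMatrix(L)))
  ob <- mkObs(vals, mask, lam)
  d <- depthValues(solveMap(L, ob$precision, ob$sparse))
  expect_lt(max(abs(d - vals)), 1e-3 * diff(range(vals)))
})

test_that("a single observation propagates to a constant map", {
  set.seed(14)
  img <- array(runif(5 * 5 * 3), c(5, 5, 3))
  L <- mattingLaplacian(img)
  mask <- matrix(FALSE, 5, 5); mask[3, 3] <- TRUE
  ob <- mkObs(matrix(4.2, 5, 5), mask, 1e3, range = c(0, 5))
  d <- depthValues(solveMap(L, ob$precision, ob$sparse))
  expect_lt(max(abs(d - 4.2)), 1e-6)
})

test_that("the sparse solve agrees with a dense direct solve", {
  set.seed(15)
  img <- array(runif(6 * 6 * 3), c(6, 6, 3))
  L <- mattingLaplacian(img)
  mask <- matrix(runif(36) < 0.4, 6, 6); mask[1, 1] <- TRUE
  vals <- matrix(runif(36, 0, 3), 6, 6)
  ob <- mkObs(vals, mask, 50, range = c(-5, 10))  # wide: raw solve may wander
  d <- depthValues(solveMap(L, ob$precision, ob$sparse))
  A <- as.matrix(laplacianMatrix(L)) + diag(as.vector(ob$precision@lambda))
  b <- as.vector(ob$precision@lambda) * ifelse(is.na(as.vector(ob$sparse@values)),
                                               0, as.vector(ob$sparse@values))
  expect_lt(max(abs(as.vector(d) - solve(A, b))), 1e-9)
  # empty observations are refused
  expect_error(solveMap(L, new("PrecisionDiag", lambda = matrix(0, 6, 6)),
                        ob$sparse), "singular|observed")
})

test_that("end-to-end depth assigns step pixels to the correct floor", {
  fx <- smallFixture("steps4")  # 32 lenses, 4 floors of 8 px, 5x5 views
  res <- estimateDepth(fx$eia, fx$config, full = TRUE)
  d <- depthValues(res$depth)
  trueA <- 1 + 0.5 * (depthValues(fx$truth) - 1.5)
  # non-edge: > 2 px from the floor boundaries and the image border
  cd <- vapply(1:32, function(c) min(abs(c - 0.5 - c(0, 8, 16, 24, 32))),
               numeric(1L))
  mask <- outer(rep(TRUE, 32L), cd > 2)
  mask[1:3, ] <- FALSE; mask[30:32, ] <- FALSE
  # correct floor: closer to its own floor's alpha than to any neighbour's
  ok <- abs(d - trueA) < 0.25  # half the floor-to-floor alpha gap
  expect_gte(mean(ok[mask]), 0.9)
})

test_that("a flat textured phantom estimates a near-constant depth", {
  fx <- smallFixture("flat")
  d <- depthValues(estimateDepth(fx$eia, fx$config))
  span <- diff(range(alphas(fx$config$alphaGrid)))
  expect_lt(stats::sd(d), 0.05 * span)
})

test_that("depth estimation is bit-reproducible", {
  fx <- smallFixture("steps4")
  d1 <- estimateDepth(fx$eia, fx$config)
  d2 <- estimateDepth(fx$eia, fx$config)
  expect_identical(depthValues(d1), depthValues(d2))
})

test_that("deeper planes never estimate a smaller mean alpha", {
  means <- vapply(c(0.9, 1.5, 2.1), function(h) {
    ph <- makeStepPhantom(2L, stepHeightMm = 0, stepWidthPx = 12L,
                          textureSeed = 8L)
    ph@heightMap[] <- h
    cfg <- CaptureConfig(lensCount = 24L, pixelsPerLens = 7L,
                         disparityGain = 1, nativePlaneMm = 1.5)
    eia <- suppressWarnings(simulateCapture(ph, cfg))
    cfgD <- depthConfig(alphaGrid = AlphaGrid(seq(0.2, 1.8, length.out = 33)))
    mean(depthValues(estimateDepth(eia, cfgD)))
  }, numeric(1L))
  expect_true(all(diff(means) > 0))
})

test_that("solver overshoot beyond the observations stays within the grid", {
  # the colour-line prior is not an M-matrix: mild over/undershoot at depth
  # discontinuities is expected, but it must stay inside the alpha grid span
  fx <- smallFixture("steps4")
  res <- estimateDepth(fx$eia, fx$config, full = TRUE)
  d <- depthValues(res$depth)
  a <- range(alphas(res$volume))
  expect_gte(min(d), a[1L] - 0.25 * diff(a))
  expect_lte(max(d), a[2L] + 0.25 * diff(a))
})
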