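# Internal numerical helpers shared across modules.

# Rec.601 luma from an (H, W, 3) array.
.luminance <- function(rgb) {
  0.299 * rgb[, , 1L] + 0.587 * rgb[, , 2L] + 0.114 * rgb[, , 3L]
}

.asRGB <- function(img) {
  if (is.matrix(img)) array(rep(img, 3L), c(dim(img), 3L)) else img
}

# Symmetric (edge-including) reflection padding of a matrix by r on all sides.
.padReflect <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  ri <- c(pmin(r:1, H), seq_len(H), H - pmin(seq_len(r), H) + 1L)
  ci <- c(pmin(r:1, W), seq_len(W), W - pmin(seq_len(r), W) + 1L)
  m[ri, ci, drop = FALSE]
}

# 3x3 (4-neighbour) Laplacian with reflect-padded borders.
.laplacian3 <- function(m) {
  p <- .padReflect(m, 1L)
  H <- nrow(m); W <- ncol(m)
  p[1:H, 2:(W + 1L)] + p[3:(H + 2L), 2:(W + 1L)] +
    p[2:(H + 1L), 1:W] + p[2:(H + 1L), 3:(W + 2L)] - 4 * m
}

# Sum over a (2r+1)^2 window at every pixel, reflect padding, via running sums.
.boxSum <- function(m, r) {
  p <- .padReflect(m, r)
  w <- 2L * r + 1L
  cs <- apply(p, 2L, cumsum)
  cs <- rbind(0, cs)
  rows <- cs[(w + 1L):nrow(cs), , drop = FALSE] -
    cs[1:(nrow(cs) - w), , drop = FALSE]
  cs2 <- t(apply(rows, 1L, cumsum))
  if (nrow(rows) == 1L) cs2 <- matrix(cs2, nrow = 1L)
  cs2 <- cbind(0, cs2)
  cs2[, (w + 1L):ncol(cs2), drop = FALSE] - cs2[, 1:(ncol(cs2) - w), drop = FALSE]
}

# Sample m at (y + dy, x + dx) for scalar dy, dx; bilinear, with a validity
# mask marking samples that fall outside the grid.
.translateBilinear <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  fy <- dy - floor(dy); fx <- dx - floor(dx)
  iy <- seq_len(H) + as.integer(floor(dy))
  ix <- seq_len(W) + as.integer(floor(dx))
  vy <- iy >= 1L & (iy + fy) <= H + 1e-9
  vx <- ix >= 1L & (ix + fx) <= W + 1e-9
  gy0 <- pmin(pmax(iy, 1L), H); gy1 <- pmin(pmax(iy + 1L, 1L), H)
  gx0 <- pmin(pmax(ix, 1L), W); gx1 <- pmin(pmax(ix + 1L, 1L), W)
  val <- (1 - fy) * (1 - fx) * m[gy0, gx0, drop = FALSE] +
         (1 - fy) * fx       * m[gy0, gx1, drop = FALSE] +
         fy       * (1 - fx) * m[gy1, gx0, drop = FALSE] +
         fy       * fx       * m[gy1, gx1, drop = FALSE]
  list(values = val, valid = outer(vy, vx))
}

# Bilinear sample of m at arbitrary (ys, xs) vectors (same length), clamped
# to the grid; returns the samples and whether clamping occurred anywhere.
.sampleBilinear <- function(m, ys, xs) {
  H <- nrow(m); W <- ncol(m)
  clamped <- any(ys < 1 - 1e-9 | ys > H + 1e-9 | xs < 1 - 1e-9 | xs > W + 1e-9)
  ys <- pmin(pmax(ys, 1), H); xs <- pmin(pmax(xs, 1), W)
  y0 <- pmin(floor(ys), H - 1L); x0 <- pmin(floor(xs), W - 1L)
  y0 <- pmax(y0, 1L); x0 <- pmax(x0, 1L)
  fy <- ys - y0; fx <- xs - x0
  v <- (1 - fy) * (1 - fx) * m[cbind(y0, x0)] +
       (1 - fy) * fx       * m[cbind(y0, x0 + 1L)] +
       fy       * (1 - fx) * m[cbind(y0 + 1L, x0)] +
       fy       * fx       * m[cbind(y0 + 1L, x0 + 1L)]
  list(values = v, clamped = clamped)
}

# Evaluate an expression with a fixed RNG seed, restoring the caller's state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Catmull-Rom resampling of the columns of a matrix onto positions xs
# (1-based, align-corners).  Edge points are linearly extrapolated so that
# affine data are reproduced exactly; cubic overshoot is not clamped here.
.catmullRomCols <- function(m, xs) {
  W <- ncol(m)
  # pad with linear extrapolations on both sides
  p <- cbind(2 * m[, 1L] - m[, 2L], m, 2 * m[, W] - m[, W - 1L])
  x0 <- pmin(pmax(floor(xs), 1), W - 1L)
  tt <- xs - x0
  i <- x0 + 1L  # index into padded columns of the left interior point
  t2 <- tt * tt; t3 <- t2 * tt
  w0 <- -0.5 * t3 + t2 - 0.5 * tt
  w1 <-  1.5 * t3 - 2.5 * t2 + 1
  w2 <- -1.5 * t3 + 2 * t2 + 0.5 * tt
  w3 <-  0.5 * t3 - 0.5 * t2
  H <- nrow(m)
  p[, i - 1L, drop = FALSE] * rep(w0, each = H) +
    p[, i, drop = FALSE] * rep(w1, each = H) +
    p[, i + 1L, drop = FALSE] * rep(w2, each = H) +
    p[, i + 2L, drop = FALSE] * rep(w3, each = H)
}

# Separable Catmull-Rom (bicubic) resize to (H2, W2), align-corners.
.resizeBicubic <- function(m, H2, W2) {
  H <- nrow(m); W <- ncol(m)
  xs <- if (W2 == 1L) 1 else seq(1, W, length.out = W2)
  ys <- if (H2 == 1L) 1 else seq(1, H, length.out = H2)
  mc <- if (W >= 2L) .catmullRomCols(m, xs) else m[, rep(1L, W2), drop = FALSE]
  if (H >= 2L) t(.catmullRomCols(t(mc), ys)) else mc[rep(1L, H2), , drop = FALSE]
}

.clip01 <- function(x) pmin(pmax(x, 0), 1)

# Stage-tagged error propagation for pipeline drivers.
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}
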