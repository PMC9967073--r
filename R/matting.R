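#' @include AllClasses.R AllGenerics.R
NULL

#' Closed-form matting Laplacian of a guide image
#'
#' Builds the sparse affinity matrix encoding the local colour-line model of
#' the guide image: for every `(2r+1)^2` window `w_k` with colour mean
#' `mu_k` and covariance `Sigma_k`, the entry for a pixel pair `(i, j)`
#' co-occurring in the window accumulates
#' `delta_ij - (1/|w_k|) * (1 + (I_i - mu_k)' (Sigma_k + eps/|w_k| Id)^-1
#' (I_j - mu_k))`.
#' The result is symmetric, positive semidefinite and has zero row sums, and
#' serves as the smoothness prior of the MAP depth densification.
#'
#' Only windows fully inside the image contribute; pixel order is
#' column-major.  All per-window statistics and the 3x3 inversions are
#' evaluated vectorised across windows.
#'
#' @param image guide image: `(H, W, 3)` array in `[0, 1]` (a matrix is
#'   treated as grey replicated over channels).
#' @param windowRadius window radius r >= 1 (default 1, i.e. 3x3 windows).
#' @param epsilon colour-covariance regulariser (default 1e-5 on `[0, 1]`
#'   intensities).
#' @return a [MattingLaplacianMatrix-class].
#' @references Levin, Lischinski and Weiss, "A closed-form solution to
#'   natural image matting", IEEE TPAMI 30(2), 2008.
#' @export
mattingLaplacian <- function(image, windowRadius = 1L, epsilon = 1e-5) {
  if (epsilon <= 0) stop("epsilon must be positive")
  r <- as.integer(windowRadius)
  if (r < 1L) stop("windowRadius must be >= 1")
  image <- .asRGB(image)
  if (any(!is.finite(image))) stop("guide image contains non-finite values")
  H <- dim(image)[1L]; W <- dim(image)[2L]
  if (H < 2L * r + 1L || W < 2L * r + 1L)
    stop("image smaller than one matting window")
  w <- 2L * r + 1L; w2 <- w * w
  n <- H * W

  # linear pixel indices of each window member, windows x w2
  cy <- (r + 1L):(H - r); cx <- (r + 1L):(W - r)
  centers <- outer(cy, (cx - 1L) * H, `+`)        # column-major linear index
  centers <- as.vector(centers)
  offs <- as.vector(outer(-r:r, (-r:r) * H, `+`))
  Widx <- outer(centers, offs, `+`)               # nWin x w2
  nWin <- length(centers)

  # per-window colour statistics
  X <- lapply(1:3, function(c) {
    ch <- image[, , c]
    matrix(ch[Widx], nWin, w2)
  })
  mu <- lapply(X, rowMeans)
  C <- matrix(0, nWin, 6L)  # s11 s22 s33 s12 s13 s23 of regularised Sigma
  C[, 1L] <- rowMeans(X[[1L]] * X[[1L]]) - mu[[1L]]^2 + epsilon / w2
  C[, 2L] <- rowMeans(X[[2L]] * X[[2L]]) - mu[[2L]]^2 + epsilon / w2
  C[, 3L] <- rowMeans(X[[3L]] * X[[3L]]) - mu[[3L]]^2 + epsilon / w2
  C[, 4L] <- rowMeans(X[[1L]] * X[[2L]]) - mu[[1L]] * mu[[2L]]
  C[, 5L] <- rowMeans(X[[1L]] * X[[3L]]) - mu[[1L]] * mu[[3L]]
  C[, 6L] <- rowMeans(X[[2L]] * X[[3L]]) - mu[[2L]] * mu[[3L]]

  # vectorised 3x3 symmetric inverse via the adjugate
  a11 <- C[, 2L] * C[, 3L] - C[, 6L]^2
  a12 <- C[, 5L] * C[, 6L] - C[, 4L] * C[, 3L]
  a13 <- C[, 4L] * C[, 6L] - C[, 5L] * C[, 2L]
  a22 <- C[, 1L] * C[, 3L] - C[, 5L]^2
  a23 <- C[, 4L] * C[, 5L] - C[, 1L] * C[, 6L]
  a33 <- C[, 1L] * C[, 2L] - C[, 4L]^2
  det <- C[, 1L] * a11 + C[, 4L] * a12 + C[, 5L] * a13

  # centred colours and Y = Sigma^-1 (I_j - mu) for every window member
  Xc <- lapply(1:3, function(c) X[[c]] - mu[[c]])
  Y1 <- (Xc[[1L]] * a11 + Xc[[2L]] * a12 + Xc[[3L]] * a13) / det
  Y2 <- (Xc[[1L]] * a12 + Xc[[2L]] * a22 + Xc[[3L]] * a23) / det
  Y3 <- (Xc[[1L]] * a13 + Xc[[2L]] * a23 + Xc[[3L]] * a33) / det

  # accumulate delta_ij - G_ij over all in-window pairs
  ii <- integer(nWin * w2 * w2)
  jj <- integer(nWin * w2 * w2)
  xx <- numeric(nWin * w2 * w2)
  pos <- 0L
  for (a in seq_len(w2)) for (b in seq_len(w2)) {
    g <- (1 + Xc[[1L]][, a] * Y1[, b] + Xc[[2L]][, a] * Y2[, b] +
            Xc[[3L]][, a] * Y3[, b]) / w2
    val <- if (a == b) 1 - g else -g
    idx <- pos + seq_len(nWin)
    ii[idx] <- Widx[, a]; jj[idx] <- Widx[, b]; xx[idx] <- val
    pos <- pos + nWin
  }
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  L <- Matrix::forceSymmetric((L + Matrix::t(L)) / 2)
  new("MattingLaplacianMatrix", matrix = L, height = H, width = W,
      windowRadius = r, epsilon = as.numeric(epsilon))
}

#' MAP densification of a sparse depth map
#'
#' Solves the linear system `(L + Lambda) d = Lambda d~` — the stationarity
#' condition of the quadratic MAP objective
#' `(d~ - d)' Lambda (d~ - d) + d' L d` — propagating the sparse
#' high-confidence observations `d~` to every pixel along the colour
#' affinities encoded in the matting Laplacian `L`.  The sparse symmetric
#' positive-definite system is solved by a direct Cholesky factorisation and
#' the relative residual `||(L + Lambda) d - Lambda d~|| / ||Lambda d~||`
#' is verified to be below `tol`.
#'
#' @param L a [MattingLaplacianMatrix-class].
#' @param precision a [PrecisionDiag-class] (zero off the observation mask).
#' @param observations a [SparseDepth-class].
#' @param tol residual contract (default 1e-8).
#' @return a [RelativeDepthMap-class] of the same shape as the guide image.
#' @export
solveMap <- function(L, precision, observations, tol = 1e-8) {
  H <- L@height; W <- L@width
  if (!identical(dim(observations@values), c(H, W)))
    stop("observation map shape does not match the Laplacian's image")
  lam <- as.vector(precision@lambda)
  dt <- as.vector(observations@values)
  dt[is.na(dt)] <- 0
  if (!any(lam > 0))
    stop("no observed pixels: the MAP system is singular")
  b <- lam * dt
  A <- L@matrix + Matrix::Diagonal(x = lam)
  d <- tryCatch(as.vector(Matrix::solve(A, b)),
                error = function(e)
                  stop("MAP system could not be solved (ill-posed): ",
                       conditionMessage(e), call. = FALSE))
  res <- sqrt(sum((as.vector(A %*% d) - b)^2)) / sqrt(sum(b^2))
  if (!is.finite(res) || res > tol)
    stop(sprintf("MAP solve residual %.3g exceeds tolerance %.3g", res, tol))
  new("RelativeDepthMap", depth = matrix(d, H, W),
      valid = matrix(TRUE, H, W), alphaRange = observations@alphaRange)
}
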