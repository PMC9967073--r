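# Shared fixtures and independent oracles, all built in code.

# Analytic band-limited light field: a superposition of fronto-parallel
# planes, each a sum of low-frequency sinusoids, sampled exactly (no
# interpolation error in the construction).  `origin` offsets the lateral
# sampling grid, which realises an exact integer translation of every view.
blViewStack <- function(nLens = 16L, nViews = 5L, fmax = 0.04, K = 6L,
                        seed = 1L, depths = c(-0.6, 0.3, 0.9),
                        origin = c(0, 0)) {
  set.seed(seed)
  ci <- nViews %/% 2L + 1L
  pix <- array(0, c(nLens, nLens, nViews, nViews, 3L))
  y <- matrix(seq_len(nLens) + origin[1L], nLens, nLens)
  x <- matrix(seq_len(nLens) + origin[2L], nLens, nLens, byrow = TRUE)
  for (ch in 1:3) {
    comp <- lapply(depths, function(d)
      list(A = runif(K, 0.02, 0.06), fy = runif(K, -fmax, fmax),
           fx = runif(K, -fmax, fmax), ph = runif(K, 0, 2 * pi), d = d))
    for (s in seq_len(nViews)) for (t in seq_len(nViews)) {
      img <- matrix(0.5, nLens, nLens)
      for (cp in comp) {
        ys <- y - cp$d * (s - ci); xs <- x - cp$d * (t - ci)
        for (k in seq_along(cp$A))
          img <- img + cp$A[k] *
            cos(2 * pi * (cp$fy[k] * ys + cp$fx[k] * xs) + cp$ph[k])
      }
      pix[, , s, t, ch] <- img
    }
  }
  new("ViewStack", views = pix, centralIndex = c(ci, ci))
}

# Crop a margin so only fully-valid pixels (all views in bounds) remain.
interiorCrop <- function(img, beta, maxoff) {
  marg <- ceiling(abs(beta) * maxoff) + 1L
  idx <- (1L + marg):(nrow(img) - marg)
  img[idx, idx]
}

# Naive per-window accumulation of the matting Laplacian (dense).
denseMattingOracle <- function(image, r = 1L, eps = 1e-5) {
  H <- dim(image)[1L]; W <- dim(image)[2L]
  n <- H * W; w <- 2L * r + 1L; w2 <- w * w
  L <- matrix(0, n, n)
  for (cy in (r + 1L):(H - r)) for (cx in (r + 1L):(W - r)) {
    ys <- (cy - r):(cy + r); xs <- (cx - r):(cx + r)
    idx <- as.vector(outer(ys, (xs - 1L) * H, `+`))
    I <- t(apply(expand.grid(ys, xs), 1L, function(p) image[p[1L], p[2L], ]))
    mu <- colMeans(I)
    Sg <- stats::cov(I) * (w2 - 1) / w2 + diag(eps / w2, 3L)
    Ic <- sweep(I, 2L, mu)
    G <- (1 + Ic %*% solve(Sg) %*% t(Ic)) / w2
    L[idx, idx] <- L[idx, idx] + diag(w2) - G
  }
  L
}

# Hand-rolled histogram entropy.
entropyOracle <- function(v, levels, lo = min(v), hi = max(v)) {
  if (hi <= lo) return(0)
  bin <- pmin(pmax(floor((v - lo) / (hi - lo) * levels), 0), levels - 1)
  p <- table(bin) / length(v)
  -sum(p * log2(p))
}

# Random layered scene with at most one layer per lateral cell (a height
# field partition) unless overlap = TRUE.
randomScene <- function(H = 6L, W = 6L, nLayers = 3L, seed = 1L,
                        fill = 0.6, overlap = FALSE, lateralScale = 0.5,
                        zPlanes = seq(0, 2, length.out = nLayers)) {
  set.seed(seed)
  occ <- array(FALSE, c(H, W, nLayers))
  colr <- array(runif(H * W * 3L * nLayers), c(H, W, 3L, nLayers))
  if (overlap) {
    occ[] <- runif(H * W * nLayers) < fill
  } else {
    pick <- matrix(sample(0:nLayers, H * W, replace = TRUE,
                          prob = c(1 - fill, rep(fill / nLayers, nLayers))),
                   H, W)
    for (l in seq_len(nLayers)) occ[, , l] <- pick == l
  }
  new("LayeredScene", zPlanes = zPlanes, occupancy = occ, colors = colr,
      lateralScale = lateralScale)
}

# Independent z-buffer projection oracle for DRC rendering: every EIA pixel
# intersects EVERY layer and keeps the nearest occupied hit (full scan, no
# early exit).  Returns the raster and the index of the struck layer
# (0 = background).  Shares only the geometry constants with the renderer.
zbufferOracle <- function(scene, display, lensCount, pixelsPerLens,
                          background = c(0, 0, 0)) {
  geo <- drcGeometry(scene, display, lensCount, pixelsPerLens)
  NL <- geo$NL; Np <- geo$Np
  raster <- array(0, c(NL[1L] * Np[1L], NL[2L] * Np[2L], 3L))
  for (ch in 1:3) raster[, , ch] <- background[ch]
  hitLayer <- matrix(0L, NL[1L] * Np[1L], NL[2L] * Np[2L])
  for (a in seq_len(NL[1L])) for (b in seq_len(NL[2L])) {
    for (i in seq_len(Np[1L])) for (j in seq_len(Np[2L])) {
      bestD <- Inf; best <- 0L
      for (l in seq_along(geo$D)) {
        Y <- geo$cu[a] - geo$poU[i] * geo$D[l] / geo$g
        X <- geo$cv[b] - geo$poV[j] * geo$D[l] / geo$g
        ri <- as.integer(round(Y / geo$s + (geo$H - 1) / 2)) + 1L
        ci <- as.integer(round(X / geo$s + (geo$W - 1) / 2)) + 1L
        if (ri < 1L || ri > geo$H || ci < 1L || ci > geo$W) next
        if (scene@occupancy[ri, ci, l] && geo$D[l] < bestD) {
          bestD <- geo$D[l]; best <- l
          raster[(a - 1L) * Np[1L] + i, (b - 1L) * Np[2L] + j, ] <-
            scene@colors[ri, ci, , l]
        }
      }
      hitLayer[(a - 1L) * Np[1L] + i, (b - 1L) * Np[2L] + j] <- best
    }
  }
  list(raster = raster, hitLayer = hitLayer)
}

# Small capture fixture shared by several files (fast: 32 lenses, 7x7 views;
# 5x5 views at this scale leave sub-pixel parallax too small for the focus
# measure to discriminate).
smallFixture <- function(name = "steps4", seed = 7L)
  endToEndFixture(name, seed = seed, lenses = 32L, viewsPerSide = 7L)
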