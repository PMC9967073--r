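#' @include AllClasses.R AllGenerics.R
NULL

#' Constructor for [DisplaySpec-class]
#'
#' Defaults describe a 4K panel section behind a 1 mm-pitch lens sheet on a
#' 6 mm spacer.
#'
#' @param pixelPitch panel pixel pitch (mm).
#' @param panelResolution integer pair of panel pixels (rows, cols).
#' @param lensArray display [LensArraySpec-class]; its `gap` is the
#'   lens-to-panel spacer thickness.
#' @export
DisplaySpec <- function(pixelPitch = 0.089, panelResolution = c(2160L, 2160L),
                        lensArray = LensArraySpec(196L, 196L, lensPitch = 1,
                                                  focalLength = 3.3, gap = 6)) {
  new("DisplaySpec", pixelPitch = as.numeric(pixelPitch),
      panelResolution = rep(as.integer(panelResolution), length.out = 2L),
      lensArray = lensArray)
}

#' Upsample a metric depth map
#'
#' Separable Catmull-Rom (bicubic) interpolation with align-corners grid
#' mapping, used to bring the view-resolution depth map up to the resolution
#' of the matching high-resolution 2D image.  The output is clamped to the
#' input's range, so no interpolation overshoot can leave it.  Expects a
#' hole-filled (fully valid) map; downsampling is refused.
#'
#' @param depth a [MetricDepthMap-class].
#' @param targetResolution integer pair `(H, W)`, each >= the source size.
#' @return the resized [MetricDepthMap-class].
#' @export
upsampleDepth <- function(depth, targetResolution) {
  tr <- rep(as.integer(targetResolution), length.out = 2L)
  d <- dim(depth@depthMm)
  if (any(tr < d))
    stop(sprintf("target %d x %d is smaller than the source %d x %d ",
                 tr[1L], tr[2L], d[1L], d[2L]), "(downsampling not supported)")
  if (all(tr == d)) return(depth)
  out <- .resizeBicubic(depth@depthMm, tr[1L], tr[2L])
  rng <- range(depth@depthMm)
  out <- pmin(pmax(out, rng[1L]), rng[2L])
  new("MetricDepthMap", depthMm = out, fit = depth@fit,
      valid = matrix(TRUE, tr[1L], tr[2L]))
}

#' @rdname upsampleDepth
#' @param image `(H, W, 3)` array; same resampling applied per channel, for
#'   bringing textures to the same grid.
#' @export
upsampleImage <- function(image, targetResolution) {
  tr <- rep(as.integer(targetResolution), length.out = 2L)
  out <- array(0, c(tr, 3L))
  for (c in 1:3) out[, , c] <- .clip01(.resizeBicubic(image[, , c], tr[1L], tr[2L]))
  out
}

# 4-connected component labels of a logical mask (0 = background).
.labelComponents <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  lab[mask] <- seq_len(H * W)[mask]  # unique seeds = linear indices
  repeat {
    up    <- rbind(lab[-1L, , drop = FALSE], 0L)
    down  <- rbind(0L, lab[-H, , drop = FALSE])
    left  <- cbind(lab[, -1L, drop = FALSE], 0L)
    right <- cbind(0L, lab[, -W, drop = FALSE])
    cand <- lab
    for (m in list(up, down, left, right)) {
      pos <- m > 0L & mask & (cand == 0L | m < cand)
      cand[pos] <- m[pos]
    }
    if (identical(cand, lab)) break
    lab <- cand
  }
  lab
}

#' Fill interior holes with Coons patches
#'
#' Each hole (connected region of `holeMask`) with a complete one-pixel
#' boundary ring inside the map is replaced by the bilinearly blended Coons
#' surface interpolating the four boundary curves of its bounding box; since
#' Coons patches reproduce bilinear (hence affine) data exactly, holes cut
#' into planar regions are restored exactly.  Holes touching the image
#' border (or whose ring intersects another hole) are filled by
#' nearest-valid propagation instead, with a warning.  Non-hole pixels are
#' never modified.
#'
#' @param depth a [MetricDepthMap-class] (or numeric matrix).
#' @param holeMask logical matrix marking hole pixels.
#' @return object of the same kind with holes filled.
#' @export
fillHoles <- function(depth, holeMask) {
  m <- if (is(depth, "MetricDepthMap")) depth@depthMm else depth
  if (!any(holeMask)) return(depth)
  H <- nrow(m); W <- ncol(m)
  lab <- .labelComponents(holeMask)
  fallback <- matrix(FALSE, H, W)
  for (id in unique(lab[lab > 0L])) {
    px <- which(lab == id, arr.ind = TRUE)
    r0 <- min(px[, 1L]); r1 <- max(px[, 1L])
    c0 <- min(px[, 2L]); c1 <- max(px[, 2L])
    ringOK <- r0 > 1L && c0 > 1L && r1 < H && c1 < W
    if (ringOK) {
      rr <- (r0 - 1L):(r1 + 1L); cc <- (c0 - 1L):(c1 + 1L)
      ringOK <- !any(holeMask[rr, c(c0 - 1L, c1 + 1L)]) &&
        !any(holeMask[c(r0 - 1L, r1 + 1L), cc])
    }
    if (!ringOK) { fallback[lab == id] <- TRUE; next }
    u <- seq(0, 1, length.out = length(rr))
    v <- seq(0, 1, length.out = length(cc))
    top <- m[r0 - 1L, cc]; bottom <- m[r1 + 1L, cc]
    left <- m[rr, c0 - 1L]; right <- m[rr, c1 + 1L]
    S <- outer(1 - u, top) + outer(u, bottom) +
      outer(left, 1 - v) + outer(right, v) -
      (outer(1 - u, 1 - v) * m[r0 - 1L, c0 - 1L] +
         outer(u, 1 - v) * m[r1 + 1L, c0 - 1L] +
         outer(1 - u, v) * m[r0 - 1L, c1 + 1L] +
         outer(u, v) * m[r1 + 1L, c1 + 1L])
    sub <- m[rr, cc]
    hole <- lab[rr, cc] == id
    sub[hole] <- S[hole]
    m[rr, cc] <- sub
  }
  if (any(fallback)) {
    warning("hole touching the image border (or another hole): ",
            "filled by nearest-valid extension")
    known <- !holeMask
    while (any(fallback)) {
      acc <- matrix(0, H, W); cnt <- matrix(0, H, W)
      for (sh in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
        kn <- matrix(FALSE, H, W); vv <- matrix(0, H, W)
        sr <- seq_len(H) - sh[1L]; sc <- seq_len(W) - sh[2L]
        okr <- sr >= 1L & sr <= H; okc <- sc >= 1L & sc <= W
        kn[okr, okc] <- known[sr[okr], sc[okc]]
        vv[okr, okc] <- m[sr[okr], sc[okc]]
        acc <- acc + vv * kn; cnt <- cnt + kn
      }
      newly <- fallback & cnt > 0
      if (!any(newly)) break
      m[newly] <- acc[newly] / cnt[newly]
      known <- known | newly
      fallback <- fallback & !newly
    }
  }
  if (is(depth, "MetricDepthMap"))
    new("MetricDepthMap", depthMm = m, fit = depth@fit,
        valid = matrix(TRUE, H, W))
  else m
}

#' Lift a metric depth map and 2D image to an RGB-D point cloud
#'
#' One point per retained pixel: `x = col * scale`, `y = row * scale`
#' (0-based indices), `z = depth`; colour from the matching 2D image.
#'
#' @param depth a [MetricDepthMap-class] (same resolution as `rgb`).
#' @param rgb `(H, W, 3)` image in `[0, 1]`.
#' @param lateralScale mm per pixel.
#' @param stride keep every `stride`-th pixel in both axes (default 1).
#' @return a [PointCloud-class].
#' @export
buildPointCloud <- function(depth, rgb, lateralScale, stride = 1L) {
  d <- dim(depth@depthMm)
  if (!all(dim(rgb)[1:2] == d))
    stop(sprintf("depth (%d x %d) and image (%d x %d) resolutions differ",
                 d[1L], d[2L], dim(rgb)[1L], dim(rgb)[2L]))
  rows <- seq(1L, d[1L], by = stride)
  cols <- seq(1L, d[2L], by = stride)
  keep <- depth@valid[rows, cols, drop = FALSE]
  ri <- rep(rows, times = length(cols))[as.vector(keep)]
  ci <- rep(cols, each = length(rows))[as.vector(keep)]
  pts <- cbind(x = (ci - 1) * lateralScale, y = (ri - 1) * lateralScale,
               z = depth@depthMm[cbind(ri, ci)],
               r = rgb[cbind(ri, ci, 1L)], g = rgb[cbind(ri, ci, 2L)],
               b = rgb[cbind(ri, ci, 3L)])
  new("PointCloud", points = pts, lateralScale = as.numeric(lateralScale),
      gridDim = as.integer(d))
}

#' Slice a point cloud into depth layers
#'
#' Uniform z-binning over `[z_min, z_max]` into `nLayers` bins; every point
#' lands in exactly one layer, and the layer planes are the bin centres.  A
#' degenerate z range collapses to a single layer.
#'
#' @param pc a [PointCloud-class].
#' @param nLayers requested layer count (>= 1).
#' @return a [LayeredScene-class] on the cloud's source lateral grid.
#' @export
layerScene <- function(pc, nLayers) {
  nLayers <- as.integer(nLayers)
  if (nLayers < 1L) stop("nLayers must be >= 1")
  p <- pc@points
  if (nrow(p) == 0L) stop("empty point cloud")
  H <- pc@gridDim[1L]; W <- pc@gridDim[2L]
  zr <- range(p[, "z"])
  if (diff(zr) <= 0) nLayers <- 1L
  if (nLayers == 1L) {
    zPlanes <- mean(zr)
    idx <- rep(1L, nrow(p))
  } else {
    edges <- seq(zr[1L], zr[2L], length.out = nLayers + 1L)
    idx <- pmin(pmax(findInterval(p[, "z"], edges, rightmost.closed = TRUE),
                     1L), nLayers)
    zPlanes <- (edges[-1L] + edges[-(nLayers + 1L)]) / 2
  }
  ri <- as.integer(round(p[, "y"] / pc@lateralScale)) + 1L
  ci <- as.integer(round(p[, "x"] / pc@lateralScale)) + 1L
  occ <- array(FALSE, c(H, W, nLayers))
  colr <- array(0, c(H, W, 3L, nLayers))
  occ[cbind(ri, ci, idx)] <- TRUE
  for (c in 1:3) colr[cbind(ri, ci, c, idx)] <- p[, 3L + c]
  new("LayeredScene", zPlanes = zPlanes, occupancy = occ, colors = colr,
      lateralScale = pc@lateralScale)
}

#' Default layer count for a metric depth map
#'
#' `ceiling(depth range / (alpha step * calibration slope))`, capped at 128:
#' one layer per depth quantum the alpha grid can resolve.
#'
#' @param depth a [MetricDepthMap-class].
#' @param alphaStep alpha-grid step size.
#' @param cap maximum layer count (default 128).
#' @return integer layer count.
#' @export
defaultLayerCount <- function(depth, alphaStep, cap = 128L) {
  v <- depth@depthMm[depth@valid]
  quantum <- abs(alphaStep * depth@fit@slope)
  if (quantum <= 0 || diff(range(v)) <= 0) return(1L)
  min(as.integer(cap), max(1L, as.integer(ceiling(diff(range(v)) / quantum))))
}

#' Rotate and zoom a point cloud
#'
#' Rigid rotation about the cloud centroid (intrinsic X, then Y, then Z
#' axes, angles in degrees) followed by uniform scaling about the centroid.
#' Point count and pairwise-distance ratios are preserved.
#'
#' @param pc a [PointCloud-class].
#' @param rotation numeric `(rx, ry, rz)` in degrees.
#' @param zoom positive scale factor.
#' @return the transformed [PointCloud-class].
#' @export
applyInteraction <- function(pc, rotation = c(0, 0, 0), zoom = 1) {
  if (zoom <= 0) stop("zoom must be positive")
  th <- rotation * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0),
              c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx
  p <- pc@points
  ctr <- colMeans(p[, 1:3, drop = FALSE])
  xyz <- sweep(p[, 1:3, drop = FALSE], 2L, ctr) %*% t(R) * zoom
  p[, 1:3] <- sweep(xyz, 2L, ctr, `+`)
  new("PointCloud", points = p, lateralScale = pc@lateralScale,
      gridDim = pc@gridDim)
}

#' Rendering geometry shared by the DRC renderer and its oracles
#'
#' All lateral coordinates are mm on the optical axis frame: lens `(a, b)`
#' sits at `((a-1) - (NL-1)/2) * pitch`, EIA pixel `(i, j)` behind it at the
#' lens centre plus `((i-1) - (Np-1)/2) * pixelPitch`, on the panel plane a
#' gap `g` behind the lens plane.  Scene cell `(r, c)` sits at
#' `((c-1) - (W-1)/2) * lateralScale` (likewise for rows).  The scene's
#' z-extent is centred on the lens array's conjugate plane
#' `z_c = f g / (g - f)` (set to `4 f` when `g <= f`), with taller scene
#' points (larger z) optically nearer: layer display distance
#' `D_l = z_c + (z_mid - z_l)`.  A ray from pixel `q` through lens centre
#' `c` meets the plane at distance `D` at lateral `c + (c - q) * D / g`.
#'
#' @param scene a [LayeredScene-class].
#' @param display a [DisplaySpec-class].
#' @param lensCount integer pair of lenses to render.
#' @param pixelsPerLens integer pair of EIA pixels per lens.
#' @return list of geometry vectors (lens centres `cu`, `cv`; in-lens pixel
#'   offsets `po`; layer order `ord` nearest-first with display distances
#'   `D`; gap `g`; scene grid offsets).
#' @export
drcGeometry <- function(scene, display, lensCount, pixelsPerLens) {
  la <- display@lensArray
  g <- la@gap; f <- la@focalLength
  zc <- if (g > f) f * g / (g - f) else 4 * f
  zmid <- mean(range(scene@zPlanes))
  D <- zc + (zmid - scene@zPlanes)
  if (any(D <= 0))
    stop("scene layers reach the lens plane; reduce the depth extent")
  ord <- order(D)  # nearest-first
  NL <- rep(as.integer(lensCount), length.out = 2L)
  Np <- rep(as.integer(pixelsPerLens), length.out = 2L)
  list(cu = ((seq_len(NL[1L]) - 1) - (NL[1L] - 1) / 2) * la@lensPitch,
       cv = ((seq_len(NL[2L]) - 1) - (NL[2L] - 1) / 2) * la@lensPitch,
       poU = ((seq_len(Np[1L]) - 1) - (Np[1L] - 1) / 2) * display@pixelPitch,
       poV = ((seq_len(Np[2L]) - 1) - (Np[2L] - 1) / 2) * display@pixelPitch,
       D = D, ord = ord, g = g, NL = NL, Np = Np,
       H = dim(scene@occupancy)[1L], W = dim(scene@occupancy)[2L],
       s = scene@lateralScale)
}

#' Render a display EIA by direction-reversal calculation
#'
#' Backward rendering of computer-generated integral imaging: for every EIA
#' pixel, one ray is cast from the pixel through its elemental lens centre
#' into the layered scene; layers are visited nearest-first and the first
#' occupied cell hit supplies the pixel's colour, after which the ray stops
#' (occlusion-aware early exit).  Rays that hit nothing get the background
#' colour.  Exactly one ray is cast per raster pixel — the count is recorded
#' in the result.  Geometry conventions are documented in [drcGeometry()].
#'
#' @param scene a [LayeredScene-class].
#' @param display a [DisplaySpec-class].
#' @param eiaPixelsPerLens integer pair; default
#'   `floor(lens pitch / pixel pitch)`.
#' @param background RGB triple in `[0, 1]`.
#' @param lensCount integer pair; default as many lenses as the panel
#'   resolution accommodates (capped by the lens-array size).
#' @return a [RenderedEIA-class].
#' @export
renderEIADRC <- function(scene, display, eiaPixelsPerLens = NULL,
                         background = c(0, 0, 0), lensCount = NULL) {
  la <- display@lensArray
  if (is.null(eiaPixelsPerLens))
    eiaPixelsPerLens <- max(1L, floor(la@lensPitch / display@pixelPitch))
  Np <- rep(as.integer(eiaPixelsPerLens), length.out = 2L)
  if (is.null(lensCount))
    lensCount <- pmin(display@panelResolution %/% Np,
                      c(la@lensCountU, la@lensCountV))
  NL <- rep(as.integer(lensCount), length.out = 2L)
  raster <- array(0, c(NL[1L] * Np[1L], NL[2L] * Np[2L], 3L))
  raster[, , 1L] <- background[1L]
  raster[, , 2L] <- background[2L]
  raster[, , 3L] <- background[3L]
  nLayers <- length(scene@zPlanes)
  rays <- 0
  if (nLayers > 0L && any(scene@occupancy)) {
    geo <- drcGeometry(scene, display, NL, Np)
    for (a in seq_len(NL[1L])) for (b in seq_len(NL[2L])) {
      rows <- (a - 1L) * Np[1L] + seq_len(Np[1L])
      cols <- (b - 1L) * Np[2L] + seq_len(Np[2L])
      done <- matrix(FALSE, Np[1L], Np[2L])
      block <- raster[rows, cols, , drop = FALSE]
      for (l in geo$ord) {
        # ray lateral position on layer l: c + (c - q) * D/g, q = c + po
        Y <- geo$cu[a] - geo$poU * geo$D[l] / geo$g
        X <- geo$cv[b] - geo$poV * geo$D[l] / geo$g
        ri <- as.integer(round(Y / geo$s + (geo$H - 1) / 2)) + 1L
        ci <- as.integer(round(X / geo$s + (geo$W - 1) / 2)) + 1L
        okY <- ri >= 1L & ri <= geo$H
        okX <- ci >= 1L & ci <= geo$W
        if (!any(okY) || !any(okX)) next
        rc <- pmin(pmax(ri, 1L), geo$H)
        cc <- pmin(pmax(ci, 1L), geo$W)
        hit <- outer(okY, okX) & scene@occupancy[rc, cc, l] & !done
        if (!any(hit)) next
        for (ch in 1:3) {
          lay <- scene@colors[rc, cc, ch, l]
          pane <- block[, , ch]
          pane[hit] <- lay[hit]
          block[, , ch] <- pane
        }
        done <- done | hit
        if (all(done)) break
      }
      raster[rows, cols, ] <- block
      rays <- rays + Np[1L] * Np[2L]
    }
  } else {
    rays <- prod(NL) * prod(Np)
  }
  new("RenderedEIA", raster = raster, lensCount = NL, pixelsPerLens = Np,
      rayCount = rays, background = as.numeric(background))
}

#' Preview perspective views of a rendered EIA
#'
#' Software stand-in for looking at the physical display from different
#' angles: for a view direction `theta` (degrees), the reverse pinhole
#' mapping selects the single pixel behind each lens whose ray leaves at
#' that angle (in-lens offset `-tan(theta) * gap / pixelPitch`, rounded),
#' giving one output pixel per lens.  Angles outside the lens acceptance
#' produce a background view with a warning.
#'
#' @param eia a [RenderedEIA-class].
#' @param display the [DisplaySpec-class] it was rendered for.
#' @param viewAngles numeric vector of horizontal angles, or a 2-column
#'   matrix of (vertical, horizontal) degree pairs.
#' @param background RGB fill for out-of-acceptance views.
#' @return list of `(NLu, NLv, 3)` view images, one per angle.
#' @export
previewViews <- function(eia, display, viewAngles, background = c(0, 0, 0)) {
  if (is.null(dim(viewAngles)))
    viewAngles <- cbind(0, as.numeric(viewAngles))
  g <- display@lensArray@gap
  pp <- display@pixelPitch
  Np <- eia@pixelsPerLens
  NL <- eia@lensCount
  ctr <- Np %/% 2L + 1L
  lapply(seq_len(nrow(viewAngles)), function(k) {
    off <- -tan(viewAngles[k, ] * pi / 180) * g / pp
    iy <- ctr[1L] + as.integer(round(off[1L]))
    ix <- ctr[2L] + as.integer(round(off[2L]))
    img <- array(rep(background, each = prod(NL)), c(NL, 3L))
    if (iy < 1L || iy > Np[1L] || ix < 1L || ix > Np[2L]) {
      warning(sprintf("view angle (%g, %g) deg outside the lens acceptance",
                      viewAngles[k, 1L], viewAngles[k, 2L]))
      return(img)
    }
    rows <- (seq_len(NL[1L]) - 1L) * Np[1L] + iy
    cols <- (seq_len(NL[2L]) - 1L) * Np[2L] + ix
    img[, , 1L] <- eia@raster[rows, cols, 1L]
    img[, , 2L] <- eia@raster[rows, cols, 2L]
    img[, , 3L] <- eia@raster[rows, cols, 3L]
    img
  })
}

#' Write / read a point cloud as PLY
#'
#' ASCII or binary little-endian PLY with `uchar` colours; the lateral scale
#' and source grid shape round-trip through header comments.
#'
#' @param pc a [PointCloud-class].
#' @param path output file.
#' @param format `"ascii"` or `"binary_little_endian"`.
#' @export
writePLY <- function(pc, path, format = c("ascii", "binary_little_endian")) {
  format <- match.arg(format)
  p <- pc@points
  hdr <- c("ply", sprintf("format %s 1.0", format),
           sprintf("comment lateral_scale %.17g", pc@lateralScale),
           sprintf("comment grid_dim %d %d", pc@gridDim[1L], pc@gridDim[2L]),
           sprintf("element vertex %d", nrow(p)),
           "property float x", "property float y", "property float z",
           "property uchar red", "property uchar green", "property uchar blue",
           "end_header")
  col8 <- round(p[, 4:6] * 255)
  if (format == "ascii") {
    rows <- sprintf("%.9g %.9g %.9g %d %d %d",
                    p[, 1L], p[, 2L], p[, 3L],
                    col8[, 1L], col8[, 2L], col8[, 3L])
    writeLines(c(hdr, rows), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    for (i in seq_len(nrow(p))) {
      writeBin(as.numeric(p[i, 1:3]), con, size = 4L, endian = "little")
      writeBin(as.raw(col8[i, ]), con)
    }
  }
  invisible(path)
}

#' @rdname writePLY
#' @return `readPLY`: the [PointCloud-class].
#' @export
readPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readLineRaw <- function() {  # byte-wise line read, works on binary streams
    out <- raw()
    repeat {
      b <- readBin(con, "raw", n = 1L)
      if (length(b) == 0L || b == as.raw(10L)) break
      out <- c(out, b)
    }
    rawToChar(out)
  }
  hdr <- character()
  repeat {
    ln <- readLineRaw()
    hdr <- c(hdr, ln)
    if (ln == "end_header") break
  }
  fmt <- sub("^format (\\S+).*", "\\1", grep("^format", hdr, value = TRUE))
  nv <- as.integer(sub("^element vertex (\\d+)$", "\\1",
                       grep("^element vertex", hdr, value = TRUE)))
  scale <- as.numeric(sub("^comment lateral_scale ", "",
                          grep("^comment lateral_scale", hdr, value = TRUE)))
  gd <- as.integer(strsplit(sub("^comment grid_dim ", "",
                                grep("^comment grid_dim", hdr, value = TRUE)),
                            " ")[[1L]])
  if (length(scale) == 0L) scale <- 1
  pts <- matrix(0, nv, 6L,
                dimnames = list(NULL, c("x", "y", "z", "r", "g", "b")))
  if (fmt == "ascii") {
    rows <- vapply(seq_len(nv), function(i) readLineRaw(), character(1L))
    sp <- do.call(rbind, lapply(strsplit(rows, "\\s+"), as.numeric))
    pts[, 1:3] <- sp[, 1:3]
    pts[, 4:6] <- sp[, 4:6] / 255
  } else {
    for (i in seq_len(nv)) {
      pts[i, 1:3] <- readBin(con, "numeric", n = 3L, size = 4L,
                             endian = "little")
      pts[i, 4:6] <- as.integer(readBin(con, "raw", n = 3L)) / 255
    }
  }
  if (length(gd) != 2L) gd <- c(nv, 1L)
  new("PointCloud", points = pts, lateralScale = scale,
      gridDim = as.integer(gd))
}
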