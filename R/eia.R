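#' @include AllClasses.R AllGenerics.R
NULL

.readRaster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported raster format: ", ext, " (use PNG or TIFF)"))
  if (is.matrix(img)) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img
}

.writeRaster <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(.clip01(img), path),
    tif = , tiff = tiff::writeTIFF(.clip01(img), path, bits.per.sample = 16L),
    stop("unsupported raster format: ", ext, " (use PNG or TIFF)"))
  invisible(path)
}

#' Construct an elemental image array from a 4D tensor
#'
#' @param pixels numeric array `(Nu, Nv, Ns, Nt, 3)` in `[0, 1]`.
#' @param layout a [LensArraySpec-class].
#' @return an [ElementalImageArray-class].
#' @export
ElementalImageArray <- function(pixels, layout) {
  new("ElementalImageArray", pixels = pixels, layout = layout,
      pixelsPerLens = as.integer(dim(pixels)[3:4]))
}

#' Load an elemental image array from a raster file
#'
#' Reads a PNG or TIFF raster, centre-crops any remainder that does not tile
#' into whole elemental images, and folds it into the 4D tensor
#' `[lens u, lens v, pixel s, pixel t, channel]`.  Rasters are never
#' resampled: a raster whose dimensions are not an exact multiple of the
#' per-lens pixel count loses a centred border instead.
#'
#' @param path PNG/TIFF file; intensities are scaled to `[0, 1]` by the
#'   reader.
#' @param layout a [LensArraySpec-class] giving the lens counts.
#' @param pixelsPerLens integer pair `(Ns, Nt)`; default
#'   `floor(raster dim / lens count)`.
#' @return an [ElementalImageArray-class].
#' @examples
#' lay <- LensArraySpec(2)
#' f <- tempfile(fileext = ".png")
#' png::writePNG(array(runif(8 * 8 * 3), c(8, 8, 3)), f)
#' eia <- loadEIA(f, lay, c(4, 4))
#' dim(pixelArray(eia))  # 2 2 4 4 3
#' @export
loadEIA <- function(path, layout, pixelsPerLens = NULL) {
  raster <- .readRaster(path)
  eiaFromRaster(raster, layout, pixelsPerLens)
}

#' @rdname loadEIA
#' @param raster numeric array `(H, W, 3)` already in memory.
#' @export
eiaFromRaster <- function(raster, layout, pixelsPerLens = NULL) {
  if (is.matrix(raster)) raster <- array(rep(raster, 3L), c(dim(raster), 3L))
  d <- dim(raster)
  nl <- lensCount(layout)
  if (is.null(pixelsPerLens)) pixelsPerLens <- d[1:2] %/% nl
  ppl <- rep(as.integer(pixelsPerLens), length.out = 2L)
  need <- nl * ppl
  if (any(need > d[1:2]) || any(ppl < 1L))
    stop(sprintf(paste0("raster %d x %d cannot tile %d x %d lenses at ",
                        "%d x %d px/lens (needs %d x %d)"),
                 d[1L], d[2L], nl[1L], nl[2L], ppl[1L], ppl[2L],
                 need[1L], need[2L]))
  off <- (d[1:2] - need) %/% 2L
  raster <- raster[off[1L] + seq_len(need[1L]), off[2L] + seq_len(need[2L]), ,
                   drop = FALSE]
  x <- raster
  dim(x) <- c(ppl[1L], nl[1L], ppl[2L], nl[2L], 3L)
  pixels <- aperm(x, c(2L, 4L, 1L, 3L, 5L))
  new("ElementalImageArray", pixels = pixels, layout = layout,
      pixelsPerLens = ppl)
}

#' Flatten an elemental image array back to its raster
#'
#' Exact inverse of the tiling in [eiaFromRaster()]: for exact tilings the
#' round trip is bit-identical.
#'
#' @param eia an [ElementalImageArray-class].
#' @return numeric array `(Nu*Ns, Nv*Nt, 3)`.
#' @export
eiaToRaster <- function(eia) {
  d <- dim(eia@pixels)
  x <- aperm(eia@pixels, c(3L, 1L, 4L, 2L, 5L))
  dim(x) <- c(d[1L] * d[3L], d[2L] * d[4L], 3L)
  x
}

#' @rdname eiaToRaster
#' @param path output PNG/TIFF path.
#' @export
saveEIA <- function(eia, path) .writeRaster(eiaToRaster(eia), path)

#' Crop to the active lens area
#'
#' Keeps a centred block of whole elemental images, dropping the outer lenses
#' (e.g. the dark rim outside the region covered by the camera relay); never
#' cuts through a lens tile.
#'
#' @param eia an [ElementalImageArray-class].
#' @param activeLenses integer pair (or scalar) of lenses to keep.
#' @return the cropped [ElementalImageArray-class].
#' @export
cropActiveArea <- function(eia, activeLenses) {
  a <- rep(as.integer(activeLenses), length.out = 2L)
  nl <- lensCount(eia)
  if (any(a > nl) || any(a < 1L))
    stop(sprintf("active area %d x %d exceeds the %d x %d lens array",
                 a[1L], a[2L], nl[1L], nl[2L]))
  off <- (nl - a) %/% 2L
  lay <- eia@layout
  lay@lensCountU <- a[1L]; lay@lensCountV <- a[2L]
  new("ElementalImageArray",
      pixels = eia@pixels[off[1L] + seq_len(a[1L]), off[2L] + seq_len(a[2L]), , , ,
                          drop = FALSE],
      layout = lay, pixelsPerLens = eia@pixelsPerLens)
}

#' Extract the orthographic view stack
#'
#' View `(s, t)` collects intra-lens pixel `(s, t)` across all lenses, giving
#' `Ns * Nt` views of `Nu x Nv` pixels each — a bijective re-indexing of the
#' elemental image array (no pixel is duplicated or dropped).
#'
#' @param eia an [ElementalImageArray-class].
#' @return a [ViewStack-class].
#' @export
extractViews <- function(eia) {
  ppl <- eia@pixelsPerLens
  new("ViewStack", views = eia@pixels,
      centralIndex = as.integer(ppl %/% 2L + 1L))
}

#' Reassemble an elemental image array from a view stack
#'
#' Inverse of [extractViews()]; the round trip is bit-exact.
#'
#' @param views a [ViewStack-class].
#' @param layout a [LensArraySpec-class].
#' @return an [ElementalImageArray-class].
#' @export
viewsToEIA <- function(views, layout) {
  new("ElementalImageArray", pixels = views@views, layout = layout,
      pixelsPerLens = as.integer(dim(views@views)[3:4]))
}

#' Fetch one view
#'
#' @param views a [ViewStack-class].
#' @param s,t 1-based view index.
#' @return numeric array `(Nu, Nv, 3)`.
#' @export
getView <- function(views, s, t) {
  views@views[, , s, t, ]
}

#' Central viewpoint image
#'
#' The view sharing the viewpoint of the refocused image set; used as the
#' guide image for the matting Laplacian.
#'
#' @param views a [ViewStack-class].
#' @return numeric array `(Nu, Nv, 3)`.
#' @export
centralView <- function(views) {
  ci <- views@centralIndex
  getView(views, ci[1L], ci[2L])
}

#' Read/write the layout sidecar
#'
#' Layout metadata travels next to the raster as a small YAML file with the
#' lens counts, per-lens pixel count, pitch, focal length and gap.
#'
#' @param path YAML file.
#' @return `readLayout`: list with `layout` ([LensArraySpec-class]) and
#'   `pixelsPerLens`.
#' @export
readLayout <- function(path) {
  y <- yaml::read_yaml(path)
  list(layout = LensArraySpec(y$lens_count_u, y$lens_count_v,
                              lensPitch = y$lens_pitch,
                              focalLength = y$focal_length, gap = y$gap),
       pixelsPerLens = as.integer(unlist(y$pixels_per_lens)))
}

#' @rdname readLayout
#' @param layout a [LensArraySpec-class].
#' @param pixelsPerLens integer pair.
#' @export
writeLayout <- function(layout, pixelsPerLens, path) {
  yaml::write_yaml(list(
    lens_count_u = layout@lensCountU, lens_count_v = layout@lensCountV,
    lens_pitch = layout@lensPitch, focal_length = layout@focalLength,
    gap = layout@gap, pixels_per_lens = as.integer(pixelsPerLens)), path)
  invisible(path)
}
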