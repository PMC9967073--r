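#' @include AllClasses.R AllGenerics.R
NULL

#' Shear per unit view-index offset for a refocus parameter
#'
#' Converts the refocus parameter alpha into the per-view image shift (in
#' view pixels per unit view-index offset from the central view) that the
#' discrete slicing trajectory applies.  Under the `linear` convention the
#' shear is `alpha - 1`, so the in-focus alpha is an affine function of
#' simulated object-space displacement; `reciprocal` uses `1 - 1/alpha`.
#'
#' @param alpha positive refocus parameter.
#' @param convention `"linear"` (default) or `"reciprocal"`.
#' @return the shear beta (view pixels per view-index unit).
#' @export
shearOfAlpha <- function(alpha, convention = c("linear", "reciprocal")) {
  convention <- match.arg(convention)
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("alpha must be positive and finite")
  if (convention == "linear") alpha - 1 else 1 - 1 / alpha
}

# Split a view stack into per-channel (Nu, Nv, Ns, Nt) arrays (keeping
# length-1 view axes that plain indexing would drop).
.channelViews <- function(views, channels) {
  v <- views@views
  d4 <- dim(v)[1:4]
  keep <- function(a) { dim(a) <- d4; a }
  if (channels == "luma")
    list(keep(0.299 * v[, , , , 1L] + 0.587 * v[, , , , 2L] +
                0.114 * v[, , , , 3L]))
  else lapply(1:3, function(c) keep(v[, , , , c]))
}

# Shift-and-sum refocusing of per-channel view arrays at shear beta.
# Out-of-bounds samples are excluded and the mean renormalised per pixel.
.refocusSS <- function(chv, ci, beta, background = 0) {
  d <- dim(chv[[1L]])
  H <- d[1L]; W <- d[2L]; Ns <- d[3L]; Nt <- d[4L]
  acc <- lapply(chv, function(.) matrix(0, H, W))
  cnt <- matrix(0, H, W)
  for (s in seq_len(Ns)) for (t in seq_len(Nt)) {
    dy <- beta * (s - ci[1L]); dx <- beta * (t - ci[2L])
    tr <- .translateBilinear(chv[[1L]][, , s, t], dy, dx)
    cnt <- cnt + tr$valid
    acc[[1L]] <- acc[[1L]] + tr$values * tr$valid
    if (length(chv) > 1L) for (c in 2:length(chv)) {
      trc <- .translateBilinear(chv[[c]][, , s, t], dy, dx)
      acc[[c]] <- acc[[c]] + trc$values * trc$valid
    }
  }
  valid <- cnt > 0
  imgs <- lapply(acc, function(a) {
    out <- matrix(background, H, W)
    out[valid] <- a[valid] / cnt[valid]
    out
  })
  list(images = imgs, valid = valid)
}

# Fourier-slice refocusing: evaluates the 2D slice of the 4D light-field
# spectrum along the shear-beta trajectory.  The angular (s, t) transform is
# evaluated analytically at the sheared frequencies, which turns the slice
# into per-view spectral phase ramps; views are zero-padded against
# wrap-around before the lateral transforms.  The sub-pixel sampling of the
# slicing trajectory uses, per axis, either the exact DFT transfer function
# of the separable linear (tent) kernel -- the same discrete slicing kernel
# as the spatial shift-and-sum path, making the two paths consistent -- or
# the ideal band-limited (sinc) kernel.
.refocusFFT <- function(chv, ci, beta, kernel = "bilinear") {
  d <- dim(chv[[1L]])
  H <- d[1L]; W <- d[2L]; Ns <- d[3L]; Nt <- d[4L]
  maxoff <- max(max(ci[1L] - 1L, Ns - ci[1L]), max(ci[2L] - 1L, Nt - ci[2L]))
  pad <- as.integer(ceiling(abs(beta) * maxoff)) + 2L
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  ramp <- function(dd, N) {
    if (kernel == "bilinear") {
      # integer part as a pure phase, fractional part as the tent kernel's DFT
      d0 <- floor(dd); fr <- dd - d0
      k <- 0:(N - 1L)
      exp(2i * pi * k * d0 / N) * ((1 - fr) + fr * exp(2i * pi * k / N))
    } else {
      k <- 0:(N - 1L); k[k > N / 2] <- k[k > N / 2] - N
      r <- exp(2i * pi * k * dd / N)
      if (N %% 2L == 0L) r[N / 2 + 1L] <- cos(pi * dd)  # real Nyquist
      r
    }
  }
  ry <- lapply(seq_len(Ns), function(s) ramp(beta * (s - ci[1L]), Hp))
  rx <- lapply(seq_len(Nt), function(t) ramp(beta * (t - ci[2L]), Wp))
  core <- pad + seq_len(H)
  corew <- pad + seq_len(W)
  lapply(chv, function(a) {
    spec <- matrix(0 + 0i, Hp, Wp)
    buf <- matrix(0, Hp, Wp)
    for (s in seq_len(Ns)) for (t in seq_len(Nt)) {
      buf[core, corew] <- a[, , s, t]
      spec <- spec + stats::fft(buf) * outer(ry[[s]], rx[[t]])
    }
    out <- Re(stats::fft(spec / (Ns * Nt), inverse = TRUE)) / (Hp * Wp)
    out[core, corew]
  })
}

# Sample-set validity mask shared by both refocusing paths (separable in
# the two lateral axes because the shift is a per-view constant).
.refocusValid <- function(d, ci, beta) {
  cy <- rep(0, d[1L]); cx <- rep(0, d[2L])
  for (s in seq_len(d[3L])) {
    iy <- seq_len(d[1L]) + beta * (s - ci[1L])
    cy <- cy + (iy >= 1 - 1e-9 & iy <= d[1L] + 1e-9)
  }
  for (t in seq_len(d[4L])) {
    ix <- seq_len(d[2L]) + beta * (t - ci[2L])
    cx <- cx + (ix >= 1 - 1e-9 & ix <= d[2L] + 1e-9)
  }
  outer(cy, cx) > 0
}

.refocusOne <- function(views, alpha, convention, method, channels,
                        background = 0, kernel = "bilinear") {
  beta <- shearOfAlpha(alpha, convention)
  chv <- .channelViews(views, channels)
  ci <- views@centralIndex
  if (method == "shift_sum") {
    .refocusSS(chv, ci, beta, background)
  } else {
    list(images = .refocusFFT(chv, ci, beta, kernel),
         valid = .refocusValid(dim(chv[[1L]]), ci, beta))
  }
}

#' Digitally refocus a view stack at one alpha
#'
#' `refocusShiftSum` shifts every orthographic view by
#' `beta(alpha) * ((s, t) - central index)` with bilinear sub-pixel sampling
#' and averages, excluding out-of-bounds samples from the per-pixel mean.
#' `refocusFourier` computes the same image through the Fourier slice
#' theorem: the 2D slice of the 4D spectrum whose trajectory corresponds to
#' `beta(alpha)` is extracted (per-view spectral phase ramps on zero-padded
#' views) and inverse-transformed.  Away from borders the two agree to
#' numerical tolerance on band-limited data.
#'
#' @param views a [ViewStack-class].
#' @param alpha positive refocus parameter.
#' @param convention shear convention, see [shearOfAlpha()].
#' @param channels `"luma"` (default) or `"rgb"`.
#' @param background fill value for pixels with an empty sample set.
#' @return list with `image` (matrix, or `(H, W, 3)` array for RGB) and
#'   logical `valid` mask.
#' @export
refocusShiftSum <- function(views, alpha, convention = c("linear", "reciprocal"),
                            channels = c("luma", "rgb"), background = 0) {
  convention <- match.arg(convention); channels <- match.arg(channels)
  r <- .refocusOne(views, alpha, convention, "shift_sum", channels, background)
  img <- if (length(r$images) == 1L) r$images[[1L]] else
    array(unlist(r$images), c(dim(r$images[[1L]]), 3L))
  list(image = img, valid = r$valid)
}

#' @rdname refocusShiftSum
#' @param kernel sub-pixel sampling kernel of the slicing trajectory:
#'   `"bilinear"` (default; the exact DFT transfer function of the tent
#'   kernel, so the spectral path evaluates the same discrete slice as the
#'   spatial path) or `"sinc"` (ideal band-limited slicing).
#' @export
refocusFourier <- function(views, alpha, convention = c("linear", "reciprocal"),
                           channels = c("luma", "rgb"),
                           kernel = c("bilinear", "sinc")) {
  convention <- match.arg(convention); channels <- match.arg(channels)
  kernel <- match.arg(kernel)
  r <- .refocusOne(views, alpha, convention, "fourier", channels,
                   kernel = kernel)
  img <- if (length(r$images) == 1L) r$images[[1L]] else
    array(unlist(r$images), c(dim(r$images[[1L]]), 3L))
  list(image = img, valid = r$valid)
}

#' Full-validity interior mask at one alpha
#'
#' Pixels whose refocus sample set is complete (every view samples
#' in-bounds).  On this region no border renormalisation takes place and the
#' spatial and spectral refocusing paths evaluate the same discrete slice.
#'
#' @param views a [ViewStack-class].
#' @param alpha refocus parameter.
#' @param convention shear convention.
#' @return logical matrix.
#' @export
refocusInteriorMask <- function(views, alpha,
                                convention = c("linear", "reciprocal")) {
  convention <- match.arg(convention)
  beta <- shearOfAlpha(alpha, convention)
  d <- dim(views@views)
  ci <- views@centralIndex
  cy <- rep(TRUE, d[1L]); cx <- rep(TRUE, d[2L])
  for (s in seq_len(d[3L])) {
    iy <- seq_len(d[1L]) + beta * (s - ci[1L])
    cy <- cy & iy >= 1 - 1e-9 & iy <= d[1L] + 1e-9
  }
  for (t in seq_len(d[4L])) {
    ix <- seq_len(d[2L]) + beta * (t - ci[2L])
    cx <- cx & ix >= 1 - 1e-9 & ix <= d[2L] + 1e-9
  }
  outer(cy, cx, `&`)
}

#' Default refocus grid
#'
#' 64 alphas uniform in shear beta.  The shear range is chosen so the largest
#' per-view shift stays within a quarter of the view width, then truncated to
#' keep alpha positive (`linear`) or the shear below 1 (`reciprocal`).
#'
#' @param views a [ViewStack-class].
#' @param steps grid size.
#' @param convention shear convention.
#' @return an [AlphaGrid-class].
#' @export
defaultAlphaGrid <- function(views, steps = 64L,
                             convention = c("linear", "reciprocal")) {
  convention <- match.arg(convention)
  d <- dim(views@views)
  ci <- views@centralIndex
  maxoff <- max(ci[1L] - 1L, d[3L] - ci[1L], ci[2L] - 1L, d[4L] - ci[2L], 1L)
  bmax <- min(d[1L], d[2L]) / 4 / maxoff
  blo <- if (convention == "linear") max(-bmax, -0.95) else -bmax
  bhi <- if (convention == "linear") bmax else min(bmax, 0.9)
  betas <- seq(blo, bhi, length.out = steps)
  a <- if (convention == "linear") 1 + betas else 1 / (1 - betas)
  AlphaGrid(a)
}

#' Build a focal stack over an alpha grid
#'
#' One refocused image per grid alpha, in grid order, with the shear
#' convention and refocusing method recorded in the object.
#'
#' @param views a [ViewStack-class].
#' @param grid an [AlphaGrid-class] (or numeric vector); default
#'   [defaultAlphaGrid()].
#' @param method `"shift_sum"` (default) or `"fourier"`.
#' @param convention shear convention, see [shearOfAlpha()].
#' @param channels `"luma"` (default, used for depth estimation) or `"rgb"`.
#' @param kernel slicing kernel of the Fourier path, see [refocusFourier()].
#' @return a [FocalStack-class].
#' @export
buildFocalStack <- function(views, grid = NULL,
                            method = c("shift_sum", "fourier"),
                            convention = c("linear", "reciprocal"),
                            channels = c("luma", "rgb"),
                            kernel = c("bilinear", "sinc")) {
  method <- match.arg(method); convention <- match.arg(convention)
  channels <- match.arg(channels); kernel <- match.arg(kernel)
  if (is.null(grid)) grid <- defaultAlphaGrid(views, convention = convention)
  if (is.numeric(grid)) grid <- AlphaGrid(grid)
  a <- grid@alphas
  d <- dim(views@views)
  C <- if (channels == "luma") 1L else 3L
  images <- array(0, c(d[1L], d[2L], C, length(a)))
  valid <- array(FALSE, c(d[1L], d[2L], length(a)))
  chv <- .channelViews(views, channels)
  ci <- views@centralIndex
  for (i in seq_along(a)) {
    r <- tryCatch({
      beta <- shearOfAlpha(a[i], convention)
      if (method == "shift_sum") .refocusSS(chv, ci, beta)
      else list(images = .refocusFFT(chv, ci, beta, kernel),
                valid = .refocusValid(dim(chv[[1L]]), ci, beta))
    }, error = function(e)
      stop(sprintf("refocusing failed at alpha = %g: %s", a[i],
                   conditionMessage(e)), call. = FALSE))
    for (c in seq_len(C)) images[, , c, i] <- r$images[[c]]
    valid[, , i] <- r$valid
  }
  new("FocalStack", images = images, alphaGrid = grid,
      convention = convention, method = method, valid = valid)
}
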