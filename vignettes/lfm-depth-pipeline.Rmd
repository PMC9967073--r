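---
title: "From elemental image array to metric depth and display EIA: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From elemental image array to metric depth and display EIA: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LFMtools)
```

This vignette is the package's account of its science: the data model, the
algorithms, every tunable that matters, the design choices that were
genuinely open, and what the synthetic test bed does and does not show
about real microscope data.

## The data model

A focused light-field microscope records a 4D light field `L(s, t, u, v)`
as an *elemental image array* (EIA): a raster tiled into one small image
per microlens. The package stores it as a 5D tensor `(Nu, Nv, Ns, Nt, 3)`
with intensities in `[0, 1]`: lens index `(u, v)` is the spatial sample,
in-lens pixel `(s, t)` the angular sample. Orthographic (sub-aperture)
*views* take the same in-lens pixel across all lenses, so views have one
pixel per lens: a 76 × 76 lens array gives `Ns·Nt` views of 76 × 76 px.
View extraction is a pure re-indexing — bijective, with a bit-exact
inverse (`viewsToEIA`).

Conventions, fixed once and used everywhere: coordinates are 0-based
`(row, col)` with the origin top-left in the documented API (R's internal
indexing is 1-based); the central view index is `floor(N/2)` 0-based, so
even counts pick the upper-left member of the central 2 × 2; rasters that
do not tile exactly are centre-cropped, never resampled, because
resampling would blur the angular samples.

## Digital refocusing

Refocusing synthesises the image at a virtual plane indexed by α (α = 1 is
the native MLA plane). Discretely, a plane corresponds to a *shear*: view
`(s, t)` is translated by `β(α) · ((s, t) − central index)` and the views
averaged. Two shear conventions are provided:

* `linear` (default): `β = α − 1`. The in-focus α is then an affine
  function of object-space displacement, which matches the linear
  depth-to-parallax coupling the calibration stage relies on.
* `reciprocal`: `β = 1 − 1/α`, the plane-parameterisation used by
  classical plenoptic refocusing.

The spatial path (`refocusShiftSum`) uses bilinear sub-pixel sampling;
samples falling outside a view are excluded and the per-pixel mean
renormalised, so image borders do not darken and bias the focus measure.
Pixels with an empty sample set get a background value and are flagged in
a validity mask.

The spectral path (`refocusFourier`) evaluates the same image through the
Fourier slice theorem: the 2D slice of the 4D spectrum along the shear
trajectory, computed as per-view spectral phase ramps on zero-padded
views (the angular transform is evaluated analytically at the sheared
frequencies, so the 4D array is never materialised). Discrete slicing
requires choosing an interpolation kernel for the trajectory's sub-pixel
samples. The default kernel is the **same separable linear (tent) kernel
as the spatial path**, applied exactly via its DFT transfer function
`e^{2πik⌊d⌋/N}((1−δ) + δe^{2πik/N})`; the two paths then evaluate the same
discrete slice and agree to machine precision wherever every view samples
in bounds (`refocusInteriorMask`). An ideal band-limited (`sinc`) kernel
is available as an option; it differs from the spatial path by the
bilinear interpolation error and by Gibbs ringing from the zero-padding
step, which on realistic small views is orders of magnitude above machine
precision — a property of the estimators, not a defect of either.

The default α grid is 64 steps uniform in β, spanning shifts up to a
quarter of the view width and truncated to keep α positive; every fixture
overrides it with a grid bracketing its own depth range, since the useful
range is specimen-dependent.

## Depth estimation

**Focus measure.** Per pixel and per stack slice: the squared response of
the 3 × 3 (4-neighbour) Laplacian, summed over a `window × window`
neighbourhood (default 9 × 9, reflect-padded). RGB stacks are scored on
Rec. 601 luminance. The window trades localisation against robustness; at
view resolutions of ~76 px, 9 px covers enough texture to be stable while
keeping step edges within a few pixels.

**Initial depth.** The per-pixel argmax over α, ties broken toward the
smallest α (documented, deterministic).

**Reliability filter.** The focus argmax is only trustworthy where the
profile has a clear peak. A pixel is kept iff (a) its peak focus value is
at least `tau` (default 1.0) times the *global median* peak — discarding
texture-poor pixels — and (b) the peak is at least `prominenceRatio`
(default 1.5) times the pixel's own mean over α — discarding flat
profiles. Kept pixels become sparse observations `d̃` with a single shared
precision `lambda` (default 1e3); all others get precision zero. If
nothing survives, the error says to lower `tau`.

**Matting Laplacian.** The smoothness prior comes from the central view:
Levin's closed-form-matting affinity. For each 3 × 3 window (radius 1,
`epsilon = 1e-5` on `[0, 1]` intensities — the standard closed-form
matting setting) with colour mean `μ` and covariance `Σ`, co-occurring
pixels `i, j` accumulate
`δ_ij − (1/9)(1 + (I_i−μ)ᵀ(Σ + ε/9·Id)⁻¹(I_j−μ))`.
The result is exactly symmetric (symmetrised in floating point), has zero
row sums by construction, and is positive semidefinite. All per-window
statistics and 3 × 3 inversions are vectorised across windows.

**MAP solve.** The densified depth minimises
`(d̃−d)ᵀΛ(d̃−d) + dᵀLd`, i.e. solves `(L+Λ)d = Λd̃`. The system is sparse,
symmetric positive definite (given one observation per connected
component) and small at view resolution (n = 5776 for 76 × 76), so the
package uses Matrix's sparse Cholesky direct solve throughout and then
*verifies* the contract `‖(L+Λ)d−Λd̃‖/‖Λd̃‖ < 1e-8` (direct solves reach
~1e-14; an iterative solver would only pay off far above this problem
scale, which `upsampleDepth` deliberately keeps out of the solve by
running depth estimation at view resolution).

A caution on ranges: because the colour-line affinity is not an M-matrix
(off-diagonal signs are unconstrained), the solution can locally over- or
undershoot the observation range near depth discontinuities — a known
matting-Laplacian behaviour. The container tolerates a bounded excess
(25% of the grid span) and the tests assert that bound; the overshoot
shrinks as texture contrast and observation density grow.

## Distance calibration and measurement

The α variation is linear in object displacement, so α converts to
millimetres by a line fitted on a staircase target of known floor heights:
an ROI per floor, a *trimmed mean* representative per ROI (central 80%,
robust to salt outliers; trim fraction configurable), and ordinary least
squares `mm = slope·α + intercept`. Both coefficients are reported (a
slope-only mode exists for strict single-coefficient replication) because
a pure scale cannot absorb the arbitrary origin of the α axis; `r²` comes
with the fit. `toMetric` applies the line per pixel; `measureRoi` reports
an ROI's mean height above a baseline and its mean absolute per-pixel
error against a reference height — the per-board accuracy statistic.

Depth-map contrast is scored by discrete entropy: quantise to `levels`
bins (default 256) over the image's own min–max range — depth maps are
not natively 8-bit — or over an absolute range for byte images, and take
the Shannon entropy of occupied bins (0 for a constant image, at most
`log2(levels)`).

## Point cloud, hole filling and DRC rendering

The metric depth map is upsampled to the 2D image's resolution by
separable Catmull–Rom (bicubic) interpolation, align-corners, with edge
rows linearly extrapolated so affine data are reproduced exactly and the
output clamped to the input's range (no interpolation overshoot can leave
it). Interior holes are replaced by Coons patches interpolating the four
boundary curves of the hole's bounding box — exact on planar regions;
border-touching holes fall back to nearest-valid propagation with a
warning. One RGB-D point per retained pixel (`x = col·scale`,
`y = row·scale`, `z = depth`) forms the cloud; `layerScene` partitions it
into uniform z-bins (default count: depth range over the α-step × slope
quantum, capped at 128 — one layer per resolvable depth quantum), and
`applyInteraction` applies centroid-centred rotation and uniform zoom.

The display EIA is rendered backward (direction-reversal): for each EIA
pixel behind each elemental lens, one ray is cast from the pixel through
the lens centre (pinhole-lens model; focal length enters only through the
conjugate-plane placement `z_c = fg/(g−f)`, with the scene's z-extent
centred on it and taller points optically nearer). Layers are visited
nearest-first with nearest-cell lookup on each layer's lateral grid —
sub-cell interpolation is deliberately out of scope — and the first
occupied hit stops the ray, which both prices occlusion correctly and
bounds work at one ray per raster pixel (the count is recorded and
asserted). `previewViews` inverts the mapping for a software stand-in of
looking at the physical display off-axis: one pixel per lens at in-lens
offset `−tan(θ)·g/pixelPitch`.

## The capture simulator

`simulateCapture` realises an occlusion-free Lambertian height field with
exactly linear depth-to-parallax coupling: view `(s, t)` samples the
texture at positions shifted by `−γ·(z − z₀)·((s,t) − central)`, so a
plane at height `z` is in focus at shear `β = γ(z − z₀)` and the true
calibration line is `mm = α/γ + (z₀ − 1/γ)`. The phantoms emulate
3D-printed targets: a 4-floor staircase with 1 mm floors for calibration,
and 1 mm triangular, 2 mm cylindrical and 3 mm square columns for
measurement. Textures are band-limited high-contrast random fields
(smoothed white noise, per-channel range-stretched) so the focus measure
has signal everywhere; additive Gaussian noise (clipped) is optional and
off in the calibration-grade fixtures. Everything is deterministic in the
seeds.

Default study conditions (`endToEndFixture`): 76 × 76 lenses, 9 × 9 views
per lens, γ = 0.5 view-px per view-index per mm, native plane mid-stair
at z₀ = 1.5 mm (bounding parallax shifts to ±3 px), 64-step α grid
bracketing each phantom's depth range by 0.2 α. Unit tests use a scaled
copy (32 lenses, 7 × 7 views): at 5 × 5 views the sub-pixel parallax is
too small for the focus profile to discriminate, which is itself a
faithful property of shape-from-focus at tiny angular baselines.

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: diffraction and the wave-optics PSF, lens
aberrations and MLA rotation/misalignment, specimen self-occlusion at
oblique views, microscope illumination falloff and sensor noise
statistics, and any nonlinearity in depth-to-disparity coupling. Results
on real captures will degrade with texture-poor specimens (the
reliability filter then keeps little, and the prior does the work) and
with depth ranges beyond the linear-parallax regime.

## Numerical choices

* Argmax ties → smallest α; centre index `floor(N/2)`; 0-based half-open
  ROIs `(x0, y0, x1, y1)`.
* Bilinear sampling throughout the spatial paths; simulator shifts beyond
  the grid are clamped with a warning.
* Reflect padding for the focus measure; window sums by running sums.
* The MAP residual contract is 1e-8; the direct solve is verified against
  it after every solve.
* A sub-grid-cell systematic bias of the focus argmax (up to ~one grid
  step) can appear because bilinear interpolation blur modulates the
  focus profile along α; it cancels in the calibration fit and floor
  assignment but means individual α values should not be read at
  finer-than-grid precision.
* PLY export rounds colours to 8 bits; binary PLY is little-endian
  float32, so coordinates round-trip to ~1e-7 relative.

## Problem sizes

The shipped tests and the acceptance script run at: 16 × 16-lens fields
for refocusing-path agreement, ≤12 × 12 guide images (dense eigensolver
cross-checks) for the matting Laplacian, 6 × 6 grids for dense-solve
agreement, the 76 × 76-lens/9 × 9-view fixtures for end-to-end floor
recovery, calibration and board measurement, and ≤8 × 8-lens scenes with
≤3 layers for exact DRC-vs-oracle comparison. These sizes exercise every
code path at full fidelity; the algorithms scale to full-sensor rasters
(e.g. 4000 × 4000 over 100 × 100 lenses) with memory dominated by the
focal stack and the sparse Laplacian.

## Known limitations

* The reliability rule (median-relative peak + prominence) and the shared
  precision `lambda` are pragmatic defaults, not estimated noise models;
  specimens with strongly varying texture contrast may need per-region
  `tau`.
* The matting prior follows colour edges; depth edges without colour
  contrast (as in uniformly textured staircases) are localised only as
  well as the focus data allow.
* MAP overshoot near discontinuities (above) — bounded but nonzero.
* The DRC renderer's nearest-cell lookup aliases for scenes far from the
  conjugate plane; layer counts above the default quantum rule do not add
  information.
* The simulator's linearity is an idealisation; with a real instrument
  the calibration line should be refitted whenever magnification or the
  MLA-to-sensor distance changes.
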