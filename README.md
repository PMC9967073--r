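# LFMtools

Depth estimation, metric shape measurement and integral-imaging rendering
for focused light-field microscopy (LFM), in R.

A focused LFM inserts a microlens array (MLA) at the image plane of an
optical microscope, so a single camera exposure records a 4D light field
`L(s, t, u, v)` as a tiled *elemental image array* (EIA): one small tile per
lens. The tile grid `(u, v)` samples space, the pixels inside a tile
`(s, t)` sample direction. From one such exposure the package recovers:

* **orthographic (sub-aperture) views** — one pixel per lens, so a 76 × 76
  lens array yields 76 × 76-px views;
* **a focal stack** by digital refocusing over a grid of refocus parameters
  α (α = 1 is the native MLA plane), via the 4D Fourier slice theorem with
  a shift-and-sum spatial path as the reference;
* **a dense relative depth map** by shape-from-focus plus propagation:
  Laplacian-energy focus measures per pixel and per α, an argmax initial
  depth, reliability filtering to a sparse high-confidence depth map `d̃`
  with diagonal precision `Λ`, and the MAP densification

      (L + Λ) d = Λ d̃

  where `L` is the closed-form **matting Laplacian** of the central view —
  a symmetric positive-semidefinite, zero-row-sum affinity matrix encoding
  the local colour-line structure of the guide image;
* **a metric depth map** through a linear distance calibration
  `mm = slope · α + intercept` fitted on a step target of known floor
  heights (ROI representatives vs known mm);
* **an RGB-D point cloud and a display EIA**: hole filling with Coons
  patches, depth layering, rotate/zoom interaction, and occlusion-aware
  backward rendering by *direction-reversal calculation* (DRC) — exactly
  one ray per display-EIA pixel, cast through its elemental lens centre,
  stopping at the first occupied depth layer.

A forward capture simulator (`simulateCapture`) produces synthetic EIAs of
textured height-field phantoms — staircases and raised columns emulating
3D-printed calibration and test boards — with exactly linear
depth-to-parallax coupling, providing ground truth for every stage.

Quality metrics included: per-ROI mean height / mean absolute error
against a reference height, and the discrete (histogram) entropy of depth
maps as a background/foreground contrast score.

## Who is this for

Microscopists and image-analysis developers working with lens-array
(integral-imaging / plenoptic) microscopes who need metrically calibrated
3D surface measurements of millimetre-scale specimens from single
light-field exposures, and a display-ready EIA for lens-array 3D monitors.

## Worked example

Simulate a capture of a 4-floor staircase (1 mm floors, 76 × 76 lenses,
9 × 9 views), estimate depth, calibrate α → mm on the floors, then measure
an independently simulated 2 mm cylinder with the same calibration:

```r
library(LFMtools)

fx <- endToEndFixture("steps4", seed = 7)
fx$eia
#> ElementalImageArray: 76 x 76 lenses, 9 x 9 px/lens (raster 684 x 684)

depth <- estimateDepth(fx$eia, fx$config)
depth
#> RelativeDepthMap: 76 x 76, alpha in [0.1012, 1.782], 100.0% valid

# one ROI per stair floor -> representative alpha values
reps <- sapply(0:3, function(k)
  roiRepresentative(depth, c(k*19 + 4, 4, k*19 + 15, 72)))
round(reps, 3)
#> [1] 0.289 0.744 1.256 1.738

fit <- fitDistanceCalibration(reps, c(0, 1, 2, 3))
fit
#> CalibrationFit: mm = 2.05732 * alpha + -0.571418  (r^2 = 0.999503, n = 4)

cyl <- endToEndFixture("cylinder2mm", seed = 7)
md <- toMetric(estimateDepth(cyl$eia, cyl$config), fit)
measureRoi(md, c(28, 28, 48, 48), referenceMm = 2)
#> RoiMeasurement: mean height 1.996 mm, mean |error| 0.006 mm vs 2.000 mm (400 px)
```

The fitted slope (2.057 mm per α unit) recovers the simulator's true line
(slope 2 = 1/disparity gain) to ~3%, with r² > 0.999; the cylinder's mean
height is recovered within 0.01 mm of its 2 mm ground truth.

From there, `buildPointCloud` + `layerScene` + `renderEIADRC` produce the
display EIA, `previewViews` synthesises oblique viewpoints, `writePLY`
exports the cloud, and `applyInteraction` rotates/zooms before
re-rendering. A thin command-line front end over the same functions is in
`inst/scripts/lfm` (subcommands `simulate`, `views`, `refocus`, `depth`,
`calibrate`, `measure`, `entropy`, `render`).

## Vignette

`vignettes/lfm-depth-pipeline.Rmd` documents the model and its
assumptions, every tunable parameter with units and defaults, the
simulator's scope, numerical choices, and known limitations.
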