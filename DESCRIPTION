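Package: LFMtools
Title: Light-Field Microscopy Depth Estimation, Metric Calibration and
    Integral-Imaging Rendering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing chain for focused light-field microscopy: elemental
    image array (EIA) handling and orthographic view extraction, digital
    refocusing over an alpha grid via the 4D Fourier slice theorem (with a
    shift-and-sum reference path), Laplacian-energy shape-from-focus,
    reliability filtering to a sparse depth map, matting-Laplacian MAP
    densification, linear distance calibration from alpha units to
    millimetres, discrete-entropy depth-map scoring, RGB-D point-cloud
    regeneration with Coons-patch hole filling, and display EIA rendering by
    occlusion-aware direction-reversal calculation (DRC). A forward
    pinhole-array capture simulator generates ground-truth phantoms with
    depth-proportional parallax for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    Matrix,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'calibration.R'
    'refocus.R'
    'depth.R'
    'eia.R'
    'matting.R'
    'estimate.R'
    'render.R'
    'synthetic.R'
    'utils-internal.R'
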