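Package: microflow
Title: Microcirculation Videomicroscopy Analysis: RBC Velocimetry and Vessel Diameter
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for intravital microcirculation video: rigid
    body-motion correction by template matching, multiscale Hessian vesselness
    segmentation with skeletonization and centerline tracing, robust principal
    component analysis (low-rank + sparse) to isolate moving red blood cells,
    blood velocity estimation from the Fourier-domain orientation of centerline
    kymographs, vessel diameter by full-width-at-half-maximum of transverse
    intensity profiles, and a longitudinal group-statistics layer. Includes a
    synthetic-video generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    png,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
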