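Package: corofuse
Title: Fusion of Intravascular OCT and Coronary CT Angiography into
    Patient-Specific 3D Coronary Artery Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds high-resolution three-dimensional coronary artery models
    by fusing lumen contours extracted from annotated intravascular optical
    coherence tomography (OCT) pullback frames with centerlines and lumen
    surface meshes derived from coronary computed tomography angiography
    (CCTA). Implements calibrated contour extraction (color thresholding,
    convex hull, periodic spline fitting), catheter twist correction by
    area-overlap optimization, carina-landmark registration onto the CCTA
    centerline using rotation-minimizing transport frames, k-d tree based
    point-cloud fusion with overlap removal, implicit surface reconstruction
    and uniform wall generation, blooming-corrected calcification handling,
    and validation metrics (vertex distance, lumen-area profiles with z-score
    normalization, percent area stenosis, linear regression summaries). A
    synthetic phantom generator provides parametric vessels with known ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    tools,
    polyclip,
    RANN,
    igraph,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse
Config/testthat/edition: 3
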