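Package: meshdeform
Title: Occlusion-Robust Tissue Surface Deformation Recovery from Scene Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous recovery of deforming tissue surfaces from per-frame
    3D scene flow, designed for stereo endoscopic scenes where surgical
    instruments occlude the target. Noisy scene flow is denoised by a
    vertex-wise least-squares strain filter based on the infinitesimal
    strain tensor; per-frame vertex positions are then estimated from a
    stacked linear system combining a dynamic term (filtered flow anchors)
    and a differential-edge smoothness term, solved as a constrained least
    squares problem with instrument depth bounds on occluded vertices.
    Includes evaluation metrics (three-point plane-projection surface
    distance, 95th-percentile Hausdorff distance, Cauchy edge strain),
    rigid ICP registration, stereo triangulation and scene-flow composition
    from disparity and optical-flow fields, mesh and flow-field file I/O
    (PLY, OBJ, Middlebury .flo, PFM, PNG), and a fully seeded synthetic
    phantom simulator so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    png,
    tibble,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
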