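Package: liverseg
Title: Semi-Automatic Liver Segmentation from Volumetric CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seed-initialised semi-automatic segmentation of the liver from
    abdominal computed tomography volumes. A subject-specific bivariate normal
    model of local intensity statistics is fitted around a single user seed,
    converted to a per-voxel liver probability map, refined by relaxation
    labeling with 8-neighbour contextual support, and optimised per slice by an
    exact s-t min-cut of a region-plus-boundary energy. Anatomical
    post-processing removes spurious nodal over-segments by exterior-angle
    gated bottleneck detection and an adjacent-slice contour-overlap
    constraint. Includes SLIVER07-style evaluation metrics (volumetric overlap
    error, relative volume difference, and symmetric surface distances with
    score transforms), MetaImage and NIfTI volume input/output, and a synthetic
    CT phantom generator for validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    igraph,
    optparse
Config/testthat/edition: 3
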