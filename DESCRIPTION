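Package: pdlroot
Title: Periodontal-Ligament-Guided Extraction of 3D Tooth Root Models from
    CBCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segments individual tooth roots from cone-beam computed
    tomography (CBCT) voxel volumes by exploiting the anatomy of the
    periodontal ligament: the sub-voxel dark shell around each root is
    thresholded, dilated with 26-connectivity into a continuous shell,
    and subtracted from a root-bone mask to isolate per-tooth seed
    regions, which are then regrown under grey-window and grey-gradient
    constraints. Includes marching-tetrahedra surface extraction to STL,
    rigid ICP registration, cemento-enamel-junction cutting, nearest-point
    RMS surface deviation, local-frame bounding-box dimension errors, the
    accompanying nonparametric and ANOVA/Bonferroni statistics, and a
    synthetic CBCT phantom generator (partial-volume tooth + ligament +
    alveolar bone) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    yaml,
    jsonlite,
    car,
    nortest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
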