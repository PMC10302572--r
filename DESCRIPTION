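Package: bactomorph
Title: Bacterial Cell-Size Morphometry and Microscope-Independent
    Initiation-Mass Cross-Validation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies rod-shaped bacterial cell size from phase-contrast
    microscopy images and cross-validates size-derived cell-cycle conclusions
    with microscope-independent population methods. Provides a closed-form
    spherocylinder shape model, a synthetic phase-contrast scene generator
    with known ground truth, threshold-based segmentation with a tunable
    auto-threshold offset that reproduces the setting-dependence of measured
    cell width, midline-based morphometry with selectable width definitions,
    a Cooper-Helmstetter steady-state model with a replication run-out
    simulator for population-averaged oriC numbers, and an initiation-mass
    workflow (growth-curve steady-state verification, mean cell mass from
    optical density and cell counts, relative initiation-mass series and
    growth-rate-trend classification across analysis settings).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    MASS,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBiology, Microscopy, Segmentation, Software
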