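Package: cardio4d
Title: Retrospective Gating, Deformable-Registration Velocimetry and
    Particle Tracking for 4-D Cardiac Light-Sheet Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-imaging computation for hybrid light-sheet/light-field
    recordings of the beating embryonic heart. Retrospectively synchronizes
    per-slice image time sequences into a 4-D volume series by estimating the
    cardiac period and relative phase shifts, estimates voxel-wise myocardial
    velocity by demons deformable image registration, tracks blood-cell
    tracers with a constant-velocity linking model, fits a polynomial flow
    centerline through pooled tracer positions, projects velocities onto the
    flow direction to detect reversal, and partitions the ventricle into
    centerline-referenced segments for wall-motion statistics. Includes a
    synthetic beating-heart phantom with exhaustive ground truth so the whole
    pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
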