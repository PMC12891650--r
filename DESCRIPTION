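Package: icangle
Title: Iliococcygeus Angle Morphometry from Levator Ani Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures the iliococcygeus angle (ICA) of the levator ani
    muscle from 3D binary segmentation masks and bony pelvic landmarks.
    Builds the landmark-based Pelvic Inclination Correction System (PICS)
    coordinate frame, slices the segmentation in five equidistant planes
    perpendicular to the PICS line, fits a first-degree polynomial through
    each hemi-slice and reports left, right and total ICA per plane.
    Aggregates expert pubococcygeus and iliococcygeus defect scores into
    none/minor/major categories, tabulates group prevalence, and runs the
    cohort inference stage (Shapiro-Wilk, one-way ANOVA, Bonferroni post
    hoc, plane-exclusion rule). Includes a voxel phantom generator with
    analytic ground truth for end-to-end validation, plain-text NIfTI-1
    and 3D Slicer fiducial I/O, and a batch pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
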