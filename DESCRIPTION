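Package: labiometry
Title: Scale-Free Width-Profile Morphometry of Bilateral Anatomical Contours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the shape of bilateral anatomical
    outlines, developed for labia minora morphometry. The longitudinal
    axis of the vaginal vestibule is divided into ten equal segments and
    the perpendicular (plumb-line) distance from the axis to each labial
    free edge is measured at the nine interior division points, giving a
    scale-free 18-value width profile (L1-L9, R1-R9) per subject.
    Derived per-subject features include adjacent-segment ratios,
    prominence-zone classification, left-right asymmetry, and a
    posterior/anterior golden-ratio index. Cohort-level tools compute
    per-segment means, ratio tables, prominence distributions, and a
    reconstructed average-shape polygon, and run a stratified two-sample
    comparison protocol (Levene's variance gate followed by pooled or
    Welch t-tests). A synthetic-cohort generator with AR(1) inter-segment
    correlation and configurable covariate effects supports simulation
    studies and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    car,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
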