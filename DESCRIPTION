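Package: snapref
Title: Scaling, Merging and Post-Refinement for Snapshot Serial Crystallography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates full reflection intensities from serial ("still")
    crystallography datasets that consist entirely of partially recorded
    reflections. Partialities are modelled as the volume fraction of a sphere
    around each reciprocal lattice point lying between the limiting Ewald
    spheres of a convergent, polychromatic beam, and per-pattern diffraction
    geometry (the nine Cartesian reciprocal-basis components) is refined by
    nonlinear least squares against iteratively merged intensity estimates.
    Includes a snapshot simulator so the whole method can be exercised without
    external data, Kabsch-style linear-cost scaling, SVD-filtered normal
    equations with Bricogne rescaling, and R-factor/partiality diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
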