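Package: femrisk
Title: DXA-Based 2D Finite-Element Hip Fracture Risk Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Patient-specific assessment of proximal-femur fracture risk from
    planar DXA data. Calibrates a linear gray-level to areal bone mineral
    density relation from per-region mean BMD values, builds a constant
    thickness plane-stress finite-element model with density-derived binned
    Young's moduli, simulates a sideways fall with a spring-mass-damper impact
    force, and converts principal strains into a per-element Risk of Fracture
    whose patient-wise maximum feeds cohort-level prognostic classification.
    Includes a synthetic femur phantom generator with known ground truth, and
    variance-inflation-factor filtering with exhaustive-subset Akaike-weight
    ranking of hip structural analysis geometry against the computed risk.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    tiff,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    png,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
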