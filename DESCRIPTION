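Package: shearTFM
Title: Traction Force Microscopy Under an External Shear Force Monopole
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs per-adhesion traction forces on an elastic
    substrate while an external shear force is applied to the cell with a
    calibrated microneedle. Because the external force introduces a force
    monopole, standard Fourier-space traction force microscopy (whose
    Green's function diverges at zero wavevector) cannot be used; the
    package implements a real-space circular-patch method that fits
    per-adhesion force vectors by unregularized least squares, together
    with a regularized Fourier Transform Traction Cytometry baseline
    (0th-order Tikhonov, generalized cross-validation) for zero-monopole
    cross-validation, particle image velocimetry for bead-image
    displacement extraction, microneedle spring-constant calibration from
    PDMS micropillar bending, and force monopole/dipole/torque time
    series. A synthetic-data generator renders fluorescent bead images
    deformed by known traction fields with ground truth so the whole
    pipeline is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
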