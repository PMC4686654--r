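Package: ccruler
Title: Coiled-Coil Molecular Rulers: Length Calibration, Hydrodynamics and
    Conservation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for treating long coiled-coils as molecular rulers.
    Converts residue counts to physical length using the canonical helical
    rise, designs register-aware nanometre-calibrated truncation constructs,
    predicts coiled-coil segments from sequence with a sliding-window heptad
    propensity score, quantifies coiled-coil length conservation across
    orthologue families, computes closed-form translational diffusion
    coefficients for stiff rods and spheres, fits single-component 3D
    diffusion models to fluorescence correlation spectroscopy
    autocorrelation curves, and measures contour lengths of digitized
    electron-microscopy particle traces. Includes seeded synthetic-data
    generators so every stage of the analysis can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
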