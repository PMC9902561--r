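Package: cfmstack
Title: Centrifuge Force Microscope Analysis of DNA Base-Stacking Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for centrifuge force microscope (CFM)
    force-clamp experiments on DNA tethers: converts centrifuge spin rates
    to tether forces, tracks tethered microspheres in image stacks via a
    circular Hough transform and intensity-variance dissociation calling,
    builds survival curves and fits the single-exponential decay
    y = y0 + A*exp(-k*t), aggregates replicate off-rates, fits the
    Bell-Evans force dependence, and extracts single base-stacking free
    energies dG = RT*ln(k1/k2) with propagated uncertainties. A synthetic
    data module generates dissociation datasets and rendered bead movies
    with known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
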