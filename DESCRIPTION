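Package: rodsfrt
Title: Virtual-Rod Spatially Fractionated Radiotherapy Boost Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Planning toolkit for a virtualised spatially fractionated
    radiotherapy (SFRT) boost built from "rod" substructures inside a target
    volume. Generates straight rod grids and spline-bent rods inside a
    clinical target volume, derives the surrounding valley (cooling)
    structure and margin expansions, produces deliverable-style heterogeneous
    dose distributions with a Gaussian-fluence surrogate optimizer
    (peak-and-valley, peak-only and uniform strategies), and evaluates plans
    with the full dosimetric chain: cumulative dose-volume histograms,
    D90/D2cm3/VxGy metrics, prescription normalisation to the 90% coverage
    level, EQD2 conversion and cumulative constraint checking, and
    coverage-mitigation renormalisation. Includes a deterministic synthetic
    pelvic-phantom generator so the whole chain runs without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    pracma,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
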