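Package: mlcray
Title: Two-Dimensional Ray Tracing of Rounded-End Multileaf Collimator
    Transmission
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the transmission of a rounded-end, linearly traveling
    multileaf collimator (MLC) leaf by two-dimensional ray tracing from a
    point source through a rectangle-plus-fitted-circle leaf profile.
    Generates transmission curves for a parked leaf at any tip position,
    extracts the characteristic beam-edge rays (tangent or visible ray,
    half-attenuation ray, boundary ray) and the derived metrics
    (radiation-to-light-field edge offset, 80-20 beam edge broadening,
    tip zone width), and locates the leaf positions at which the
    quasi-static constancy assumption behind light-field position
    calibration breaks down, including sweeps of the break position
    versus leaf tip radius.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
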