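Package: couchalign
Title: EPID-Based Alignment of the Linac Table Rotation Axis with
    Radiation Isocenter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "qa@example.org", role = c("aut", "cre"))
Description: Measures and corrects the alignment of a linear-accelerator
    treatment-table rotation axis with the megavoltage radiation isocenter
    using electronic portal imaging device (EPID) images. Implements the
    eight-image ball-bearing placement procedure, sub-pixel centroid
    fitting of the BB shadow, trajectory analysis over table rotation with
    a Kasa least-squares circle fit, conversion of the prescribed
    adjustment into table-base fixing-screw rotations, longitudinal
    tracking of maximum rotational error, and a deterministic virtual
    linac simulator for closed-loop validation of the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    tiff,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
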