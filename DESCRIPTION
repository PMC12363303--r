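Package: blebmetrics
Title: CT Morphometry and Pressure Analysis of Large-Volume Subcutaneous Injections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize large-volume subcutaneous injections from
    CT image series and inline pressure recordings. Segments the
    contrast-filled injection bleb by seeded threshold region growing,
    measures its semi-axes and ellipsoid-approximation surface area over a
    scan schedule, quantifies skin distension by pre/post skin-surface
    overlay with a half-ellipsoid volume model, and analyzes subcutaneous
    pressure traces (peak detection near injection cessation,
    double-exponential decay fitting, effective decay constant). Includes a
    synthetic phantom and pressure-trace generator with ground truth, and an
    experiment pipeline replicating a two-volume, with/without-hyaluronidase
    study design with group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
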