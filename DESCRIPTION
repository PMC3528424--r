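Package: needlefield
Title: Analytical Electric-Field Modelling for Needle-Electrode
    Electroporation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Closed-form electrostatic modelling of the electric field
    established by parallel needle-electrode pairs in a two-dimensional
    tissue slice, as used in treatment planning for electrochemotherapy
    and non-thermal irreversible electroporation. Implements the
    method-of-images two-conductor potential with eccentric electrical
    axes, pointwise maximum composition over multi-electrode group
    configurations on a rectangular mesh, reversible/irreversible
    threshold coverage statistics for tumor and surrounding tissue,
    colour-mapped raster rendering, an independent finite-difference
    Laplace oracle for validation, and a JSON/YAML configuration layer
    with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
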