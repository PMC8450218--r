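Package: pennate
Title: Measurement and Growth Modelling of 3D Unipennate Muscle Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with digitized 3D muscle fascicle architectures of
    primarily unipennate skeletal muscles. Raw digitizer polylines are smoothed by
    quadratic fitting and resampled to 20 equidistant points; a muscle coordinate
    frame is derived by principal component analysis of fascicle endpoints; and the
    standard architectural parameters (fascicle length, pennation and transversal
    angles, aponeurosis dimensions, muscle height, belly dimensions, volume via an
    alpha-complex boundary with a shrink factor, mass, and physiological
    cross-sectional area) are measured. A four-parameter geometric growth model
    (belly length scaling with a correction factor, two-sided belly width scaling,
    homogeneous fascicle lengthening proportional to line-of-action distance, and
    fascicle rotation about midpoints) predicts the complete fascicle architecture
    at a different age or size. Includes a synthetic unipennate-muscle generator
    with analytic ground truth, comparison utilities for relative prediction
    errors, ggplot2 visualisations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
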