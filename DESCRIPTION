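Package: cytostretch
Title: Dielectrophoretic Cell Stretching and Actin Cytoskeleton Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterize single-cell biomechanics from dielectrophoresis (DEP)
    based cell stretching. Computes the applied DEP force three independent ways
    (equivalent dipole moment, simplified parallel-field approximation, and full
    Maxwell-stress-tensor integration over a numerically solved quasi-electrostatic
    field in a 2D microfluidic chip cross-section), simulates cell deformation with
    a coarse-grained worm-like-chain actin network model crosslinked by Hookean
    actin-binding-protein springs, and fits strain-force curves to recover
    cytoskeletal structural parameters and apparent elastic moduli.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
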