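Package: celldose
Title: Cellular Dosimetry and Bioeffect Modeling for Radiolabeled Cell
    Populations
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Absorbed-dose and cell-survival modeling for single cells,
    cell pairs, planar colonies, and three-dimensional clusters of cells
    labeled with alpha-, beta-, or Auger-electron-emitting
    radiopharmaceuticals.  Cells are modeled as two concentric spheres
    (cell and nucleus) of unit-density water; cellular self- and
    cross-dose S coefficients are computed with analytic range-energy
    point kernels for electrons and alpha particles, validated against a
    built-in straight-line Monte Carlo estimator.  Activity can be
    distributed among labeled cells uniformly, normally, lognormally, or
    by radial profiles with a drug-penetration cold core.  Survival is
    modeled with simple or radiation-type-resolved linear-quadratic
    models, and tumor control probability is computed by Poisson and
    per-cell product formulations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
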