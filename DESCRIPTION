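Package: smforce
Title: Single-Molecule Force Spectroscopy and AFM Morphometry of Amyloid
    Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-molecule atomic force spectroscopy
    (AFS) pulling experiments and AFM topographs of aggregating peptides.
    Includes cantilever calibration (contact-slope sensitivity, thermal-tune
    spring constant), worm-like-chain rupture-event extraction from
    force-distance curves, double-Gaussian rupture-force histogram fitting
    with effective-counts standard errors, a Poisson multiple-tether discard
    correction, and quantification of aggregate morphology (oligomer, fibril,
    amorphous) from height images. A synthetic-data module generates force
    curves, thermal deflection series and topographs with known ground truth
    so every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
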