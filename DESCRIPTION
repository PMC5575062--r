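Package: gcflow
Title: Quantification of Growth-Cone Cytoskeletal Dynamics from Time-Lapse
    Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Kymograph-based measurement of retrograde F-actin treadmilling
    speed in neuronal growth cones, counting of EB3 plus-end comets entering
    neurites, EB3 signal coverage of reporter-covered growth-cone area,
    automatic mean-threshold delineation of growth cones with per-frame
    intensity retrieval, standard-score correlation and group-comparison
    statistics, and fitting of pyrene actin polymerization kinetics (plateau
    and half-time).  A synthetic time-lapse and kinetics generator with known
    ground truth makes every stage verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    multcomp,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
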