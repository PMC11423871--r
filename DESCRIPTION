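Package: nemspindle
Title: Nematic Liquid-Crystal Analysis of Oocyte Spindle Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of polarized-light (LC-PolScope) and confocal
    microscopy of metaphase-II oocyte spindles under a nematic liquid-crystal
    model. Provides rigid registration of retardance/slow-axis movies,
    pole-indented-tactoid boundary fitting, the circle-arc nematic director
    field, orientational fluctuation spectra with mirror padding, inversion of
    retardance profiles into microtubule density and average void shape,
    metaphase-plate chromosome segmentation and edge-corrected pair
    correlation functions, an analytic two-dimensional defect-quadrupole model
    of void-void repulsion, and Metropolis Monte Carlo simulations of
    hard-ellipse chromosome configurations under long-range repulsive
    potentials. Synthetic-data generators with known ground truth make every
    stage testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    Rcpp,
    generics,
    EBImage,
    tiff,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
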