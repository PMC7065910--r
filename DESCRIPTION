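Package: unwindr
Title: Single-Molecule Helicase Unwinding Analysis from Kymographs and Force Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for correlated optical-tweezers and confocal
    fluorescence measurements of helicase-catalysed DNA unwinding. Provides
    closed-form polymer elasticity models (extensible freely jointed chain for
    ssDNA, extensible worm-like chain for dsDNA) and their inversion and
    fitting; tether-geometry bookkeeping that converts constant-force
    tether-length changes and Sytox dark-region spans into base pairs unwound;
    a calibrated synthetic kymograph generator with Poisson photon noise,
    point-spread-function blur and ground truth; dark-region segmentation,
    edge and fluorescent-spot tracking; and event-level inference:
    unidirectional versus bidirectional classification, linear-region rate
    fitting in bp/s, required-initiation-force tallies, rewinding detection,
    and condition-level summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
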