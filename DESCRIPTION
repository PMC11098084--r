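Package: chrompair
Title: Brownian-Dynamics Simulation of Homolog Pairing by Nonspecific Button Barcodes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coarse-grained bead-spring worm-like-chain simulation of
    chromosome arms confined to a spherical nucleus with Rabl centromere
    tethering, in which nonspecific adhesive buttons arranged in
    chromosome-specific spacing patterns (button barcodes) produce selective
    homolog pairing. Provides the overdamped Langevin integrator, reversible
    button-pairing kinetics, barcode constructors and editors (uniform,
    random, industrial code 2 of 5, inversion, shifts, translocations),
    pairing-fidelity and kymograph analysis, persistence-length and Rabl
    correlation estimators, discrimination-energy calculations, and preset
    scenario ensembles with figure-style outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
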