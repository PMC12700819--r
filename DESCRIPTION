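Package: chromodyn
Title: Coupled Loop-Extrusion and Block-Copolymer Simulation of
    Chromosome Organization Across the Mitosis-to-G1 Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates chromatin organization at the mitosis-to-G1
    transition by coupling a discrete 1D lattice model of SMC loop
    extrusion (condensin I/II, cohesin, CTCF stalling) to overdamped
    Langevin dynamics of a typed A/B/C block-copolymer chain under
    spherical or cylindrical confinement, with a minutes-based event
    schedule for extruder exchange, compaction and affinity activation.
    Provides the accompanying contact-map statistics (ICE balancing,
    contact-probability scaling and its derivative, local-background and
    observed/expected loop strengths, aggregate peak analysis,
    compartment eigendecomposition, loop-anchor classification), a
    PCA-based classifier of transcriptionally spiking genes from Pol II
    time courses, and seeded synthetic-data generators for annotations,
    contact maps and signal tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
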