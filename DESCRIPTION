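Package: chromofold
Title: Hi-C Restraint-Based Chromosome Polymer Folding and 3D
    Colocalization Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Folds a single chromosome as a bead-spring polymer under
    harmonic restraints derived from a Hi-C contact matrix (FENE bonded
    potential with a repulsive Lennard-Jones core, Monte Carlo restraint
    satisfaction, Langevin-thermostatted Brownian dynamics in reduced
    units), maps ChIP-seq peak tracks onto the folded beads, and
    quantifies 3D colocalization of genomic marks with radial
    distribution functions, peak co-occupancy counting, and the Van
    Steensel shifted-Pearson cross-correlation statistic for two-channel
    images. Includes a synthetic-data generator (reference compartment
    structures, contact maps, peak tracks, image pairs) so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
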