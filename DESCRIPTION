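Package: sf3b1clones
Title: Clonal Dynamics, Phylogeny Dating and Genotype-Aware Splicing for
    Co-Resident SF3B1-Mutant Clones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for bone-marrow samples carrying two
    co-resident SF3B1-mutant clones. Fits replicator (logistic
    competition) models to longitudinal ddPCR variant-allele-frequency
    trajectories, tests colony-genotype enrichment against bulk
    expectations with exact binomial tails, reconstructs perfect
    phylogenies from binary colony-by-variant mutation matrices and
    dates driver acquisition in years under a somatic molecular clock
    with exact Poisson intervals, and computes per-clone percent
    spliced-in (PSI/dPSI) from splice-junction counts with cryptic-event
    classification (SE, A3SS, A5SS, RI, MXE), common/mutation-biased
    filtering and reading-frame consequence annotation. A seeded
    synthetic-data generator reproduces the statistical structure of the
    study design (two-clone competition sampled with droplet noise,
    compartment-specific colony genotypes, Poisson mutation accrual,
    planted splicing events) so every stage runs and is testable without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    ape,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
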