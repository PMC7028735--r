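Package: mosaicLOY
Title: Quantification of Mosaic Loss of Chromosome Y from SNP Arrays,
    Sequencing Read Depth and Droplet Digital PCR
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify mosaic loss of chromosome Y (LOY) in bulk
    blood DNA through three independent readouts: the median Log R Ratio of
    male-specific-region probes on SNP genotyping arrays (mLRRY) with
    kernel-density batch correction, chromosome-Y median ploidy from
    GC/mappability-corrected windowed sequencing read counts, and the
    Poisson-corrected AMELY/AMELX concentration ratio from droplet digital
    PCR. Implements the power-law calibration linking antiloged mLRRY to
    measured Y fraction, the resulting transformation of mLRRY into
    percentage of cells with LOY and its inverse, a published comparison
    formula, longitudinal trajectory classification of serially sampled
    subjects, and a fully seeded synthetic-cohort generator so every
    estimator is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    sandwich,
    lmtest,
    knitr
Config/testthat/edition: 3
biocViews: CopyNumberVariation, SNP, Sequencing, ddPCR, Software
RoxygenNote: 7.3.3
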