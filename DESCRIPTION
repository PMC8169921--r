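Package: repeatcomp
Title: Homotypic Retrotransposon Clustering and Hi-C Compartment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for relating interspersed-repeat density to chromatin
    compartmentalization. Builds binned L1 and B1/Alu density tracks from
    RepeatMasker annotations, calls A/B-like compartments de novo from the
    log2 ratio of background-normalized B1 to L1 densities, and scores the
    calls against Hi-C annotated compartments. Computes Hi-C contact-matrix
    statistics (distance-decay expectation, observed/expected, correlation
    matrix and compartment eigenvector, saddle-plot compartment strength,
    homotypic/heterotypic segregation index, cross-sample compartment
    conservation) and the image-based segregation index of two-channel
    nuclear FISH signals. Ships planted-truth simulators for repeat genomes,
    plaid contact matrices and nuclear images so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'genome-repeats.R'
    'compartments.R'
    'io.R'
    'hic.R'
    'image.R'
    'simulate.R'
    'pipeline.R'
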