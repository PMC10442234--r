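Package: nucenv
Title: Population-Based 3D Genome Modeling and Nuclear Microenvironment Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Deconvolves ensemble Hi-C contact probabilities into a population
    of diploid 3D genome structures by iterative assignment/modeling
    (A-step/M-step) optimization under nuclear-volume, excluded-volume and
    chain-connectivity constraints, and analyses the resulting structure
    population: chromatin interaction networks and their Markov-clustering
    spatial partitions, predicted nuclear speckle and nucleolus locations,
    seventeen per-region structural features describing the nuclear
    microenvironment (radial position, local compaction, body distances and
    association frequencies, simulated TSA-seq signals, inter-chromosomal
    neighborhood statistics and their cell-to-cell variability), group-wise
    feature enrichment, ROC discrimination, and unsupervised structure-based
    subcompartment classification. Includes a synthetic-data module that
    generates toy genomes and ground-truth structure populations with planted
    nuclear architecture for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    Rcpp,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
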