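Package: DefenseKit
Title: Quantitative Analysis of Anti-Phage Defense Systems and Their Mobile
    Genetic Elements
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying bacterial anti-phage defense from plaque
    and liquid-culture assays, and for cataloguing the genomic context of
    defense systems. Implements titer and efficiency-of-plating (EOP)
    estimation from serial-dilution spot assays with explicit censoring,
    plaque-size fold change and protection classifiers, epistatic
    (synergy) coefficients between co-encoded defense systems with the
    associated zeroing rule, growth-curve processing (baseline
    subtraction, area under the curve, confidence bands, reporter-dye
    normalization) and an additive-expectation AUC synergy call,
    defense-island deduplication by greedy protein-family clustering and
    gene-content grouping, and detection of tRNA-anchored integrated
    mobile genetic elements flanked by short direct repeats, with a
    keyword-based mobility classifier. Seeded synthetic-data generators
    (Poisson dilution series, a susceptible-infected-phage ODE for
    infection growth curves, genomes with planted elements, island tables
    with planted families) provide ground truth for end-to-end recovery
    testing.
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
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    deSolve,
    igraph,
    multcomp,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    knitr
biocViews: Software, Genetics, Sequencing, StatisticalMethod
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
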