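Package: cohesinHiC
Title: Hi-C Compartment and Local-Interaction Analysis of Cohesin Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for studying how loss of the cohesin subunit
    RAD21 reshapes three-dimensional genome organization in post-mitotic
    neurons. Builds binned Hi-C contact matrices from valid-pair files,
    applies Knight-Ruiz matrix balancing, derives oriented A/B compartment
    eigenvector scores, quantifies local gene-body interactions at 5 Kb
    resolution, performs ranked-bin differential-compartment feature
    analysis, classifies enhancers from ChIP-seq peaks with rule-based
    intergenic assignment, quantifies 3D DNA-FISH probe distances from
    image volumes, and provides the nonparametric statistics used
    throughout (sign test, Mood's median test, Benjamini-Hochberg
    correction, Kruskal-Wallis with Dunn's post hoc, correlation t-test).
    Includes a synthetic-data generator that plants known compartment
    flips, loop depletions and differential expression so every stage is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    data.table,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
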