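Package: rixnet
Title: Genetically Driven Co-Expression Modules in Recombinant Inbred Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A systems-genetics pipeline for discovering genetically driven
    co-expression modules in recombinant inbred (RI) panels. Covers
    strain-aware transcriptome assembly (high-confidence filtering,
    cross-strain transcript merging, gene grouping, iterative coverage-based
    reduction), microarray probe integrity masking and probe-set to gene
    cluster mapping, unsigned weighted co-expression networks with
    topological overlap and dynamic tree cutting, module eigengene QTL
    mapping with permutation-based genome-wide thresholds, partial
    correlation adjustment for shared cis loci, gene-set overrepresentation
    testing, phenotypic QTL overlap, and cell-type characterization by
    two-way ANOVA. Includes a synthetic-data generator that emulates the
    statistical structure of a two-progenitor RI study so that every stage
    can be exercised and scored against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    mclust,
    fgsea,
    IRanges,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
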