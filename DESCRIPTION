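Package: ddcat
Title: Data-Driven Categorization of Somatic Mutations for Mutational
    Signature Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for constructing and optimizing mutation categorizations
    for mutational signature analysis. Mutations are represented as 7-mer
    mutation sequences (three flanking bases on each side of a pyrimidine-
    collapsed single base substitution) and grouped into 96 categories
    described by a degenerate IUPAC pattern language. The package builds
    mutation catalogs from reference genomes and somatic mutation tables,
    extracts signatures by Kullback-Leibler non-negative matrix
    factorization, refits exposures by non-negative least squares with
    mutation-opportunity normalization between whole-genome and whole-exome
    regimes, scores categorizations by cross-validated regularized canonical
    correlation against DNA-damage-repair gene expression, and searches
    categorization space with a genetic algorithm. A synthetic-data module
    generates fully self-contained genomes, cohorts and expression matrices
    with planted signatures for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
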