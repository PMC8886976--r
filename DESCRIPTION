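Package: tadcnv
Title: TAD-Aware Functional Annotation and Pathogenicity Ranking of Copy-Number Variants
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Annotates copy-number variants (deletions and duplications) with
    functional features restricted to their topologically associating domain
    (TAD) environment, trains and applies a random-forest pathogenicity
    classifier with out-of-bag bookkeeping, ranks candidate variants against
    size-matched controls, measures permutation feature importance over
    correlated-feature clusters, and runs isochore-constrained bootstrap
    enrichment tests of CNV sets against genomic annotation tracks. Includes
    a toy-genome simulator so the full pipeline is testable without any
    external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Rcpp,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    VariantAnnotation,
    SummarizedExperiment,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
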