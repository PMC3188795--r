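Package: haploquant
Title: Haplotype- and Isoform-Specific Expression from Multi-Mapping RNA-Seq Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous estimation of haplotype- and isoform-specific
    expression from RNA-seq reads that align to multiple transcripts.
    Reads are collapsed into transcript-set counts (an indicator matrix M
    with counts k) and expression is estimated under a Poisson model by
    expectation-maximization and by Poisson-Gamma Gibbs sampling with
    Monte Carlo standard errors. Includes construction of individualized
    and hybrid (two-haplotype) transcriptome references from phased
    variant calls, best-mismatch-stratum and insert-size alignment
    filters, a Poisson-regression sequence-bias model yielding adjusted
    effective transcript lengths, amalgamation of identical-sequence
    transcripts, gene and haplo-gene aggregation, and a seeded read
    simulator with exhaustive enumeration oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    BiocGenerics,
    Biostrings,
    Rsamtools,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown,
    optparse,
    rtracklayer,
    vcfR,
    withr
LinkingTo:
    Rcpp
Config/testthat/edition: 3
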