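Package: mossmeth
Title: Whole-Genome Bisulfite Sequencing Methylome Analysis with a
    Ground-Truth Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale implementation of a plant whole-genome
    bisulfite sequencing (WGBS) methylome pipeline: three-letter
    converted-read alignment, CG/CHG/CHH context- and subcontext-resolved
    methylation calling, 50-bp window summaries, differential methylation
    with a percent-change statistic and Fisher's exact test, transposable
    element and chromatin meta-analyses, and Sanger-clone amplicon scoring.
    A synthetic genome/methylome/read simulator with genotype knockout
    effects provides known ground truth so every stage is verifiable
    without deposited sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Rsamtools,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
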