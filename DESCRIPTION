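Package: repeatscape
Title: Repeat Landscapes from Unassembled Shotgun Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Characterizes the repetitive fraction of a genome directly from
    low-coverage shotgun reads, without an assembly. Reads are quality
    filtered, subsampled to a target coverage and clustered into repeat
    families via an all-to-all similarity graph; each cluster is assembled
    into consensus contigs, annotated against a repeat library, and scored
    for average pairwise nucleotide diversity (theta-pi) and copy number
    from read pileups. Per-family copy-number decay with divergence is fit
    under a steady-state birth-death model to estimate repeat half-lives
    and classify expansion dynamics, and ancestor-descendant haplotype
    networks summarize recent proliferation. A transposable-element
    proliferation simulator with exact ground truth supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    IRanges,
    methods,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
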