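Package: syntenica
Title: Synteny Conservation and Gene Colinearity Statistics for Genome Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics for comparing gene organisation between two annotated
    genome assemblies. Implements reciprocal-best-hit ortholog pairing from
    BLAST tabular similarity searches, scaffold-by-scaffold ortholog-sharing
    contingency tables, the chi-square-derived synteny correlation
    coefficient, pairwise scaffold synteny Z-scores against a randomised
    re-association null, conserved-adjacent-ortholog (CPAO) colinearity
    counts with a genome-wide gene-order reshuffling null, and genome
    landscape summaries (sliding-window GC content, telomeric repeat array
    detection at scaffold ends, repeat-interval clustering). A genome-pair
    rearrangement simulator (inversions, transpositions, translocations,
    fusions, fissions, gene loss and gain) provides ground-truth fixtures so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    S4Vectors,
    methods,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
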