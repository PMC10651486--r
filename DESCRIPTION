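Package: srutools
Title: Discovery of Solitary CRISPR Repeat Units in Mobile Genetic Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects solitary repeat units (SRUs) - single CRISPR-repeat-like
    sequences that are candidate RNA anti-CRISPRs - in viral, prophage and
    plasmid genomes. The pipeline masks high-confidence open reading frames,
    searches a reference database of CRISPR direct repeats against the
    intergenic sequence with a short-word local aligner, resolves overlapping
    hits by bit score, clusters repeat matches into arrays, flags mini-arrays
    and self-similar flanks, and applies a calibrated bit-score threshold.
    Downstream permutation statistics test co-localization of SRUs with
    anti-CRISPR (acr) genes and association between SRU subtypes and host
    cas-operon subtypes. A seeded synthetic-genome benchmark generator with
    planted ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    rpart,
    optparse,
    withr
Config/testthat/edition: 3
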