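Package: telomotif
Title: De Novo Telomeric Repeat Motif Discovery and Telomere Variation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects telomeric repeat motifs de novo from assembled genomes or
    unmapped sequencing reads by scoring candidate kmers in chromosome-terminal
    windows (score = kmer length times repeat count), running an all-pairs
    tournament with a substring penalty, and ranking rotation-canonical motif
    classes by the number of supporting chromosome ends. Given a motif, locates
    assembled telomeric arrays, extracts the gap sequences between exact motif
    copies, aligns each gap to the motif with a custom mismatch penalty, and
    classifies single-base changes, deletions and insertions, reporting per-end
    variant frequencies, type proportions and positional profiles. Includes a
    seedable simulator of genomes and reads with known telomeric structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    Rsamtools,
    stringr,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
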