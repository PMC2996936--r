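Package: srnascan
Title: Small RNA Targeting of Transposable Elements and
    Methylation-Footprint Dating
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Consolidates small RNA (sRNA) sequencing libraries into an
    abundance database of distinct sequences, exhaustively maps perfect
    sRNA matches onto genomic and transposable-element (TE) sequences
    with a 1-nt scrolling window over all read lengths, and profiles the
    matches: per-feature densities, 21-nt versus 24-nt size classes,
    nested-insertion contrasts, and positional (decile) distributions
    within elements with chi-square uniformity tests. Classifies every
    site of a pairwise-aligned orthologous sequence pair into cytosine
    methylation contexts (CG, CHG, CHH on either strand) and tallies
    transitions and transversions at potentially methylated sites, the
    mutational footprint of RNA-directed DNA methylation. Dates sequence
    divergence and LTR retrotransposon insertions with the Kimura
    two-parameter model. A synthetic-data generator produces repeat-rich
    genomes with nested TEs, sRNA libraries with bimodal length structure
    and terminal-repeat targeting, and diverged orthologous pairs with
    elevated transition rates at methylated sites, so the whole pipeline
    is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
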