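Package: nascentscape
Title: Nascent-Transcriptome Analysis of GRO-seq Signal Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies nascent transcription from strand-specific GRO-seq
    coverage tracks and carries the analysis through to regulatory biology:
    FPKM quantification and expression filtering, exact negative-binomial
    differential-transcription tests with Benjamini-Hochberg correction,
    alternative transcription-start-site (TSS) activity and switching at
    multi-TSS loci via an adjacent-difference statistic, classification of
    lncRNAs into promoter- and enhancer-associated classes from H3K4me3 and
    H3K4me1 peaks plus super-enhancer overlap, guilt-by-association GO
    inference and hub-miRNA networks, and PWM motif enrichment at TSS windows
    correlated with transcription-factor expression. A bundled synthetic-data
    generator produces a complete input bundle (genome, annotation, stranded
    bedGraph signal, chromatin peaks, motifs, GO and miRNA-target tables) with
    machine-readable ground truth, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    ape,
    stats,
    utils,
    yaml,
    jsonlite,
    digest,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
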