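Package: dripdsb
Title: Break-Centered DRIP-seq Analysis of Damage-Induced R-Loops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies DNA:RNA hybrid (R-loop) formation around
    endonuclease-induced double-strand breaks from DRIP-seq data.  Computes
    per-nucleotide read coverage in fixed windows centered on annotated
    AsiSI cut sites, normalizes to library size, forms the per-nucleotide
    log2 fold change between damaged (+OHT) and undamaged (-OHT)
    conditions, reduces each site to a 1-kb induction score, and runs
    grouped rank-sum comparisons (repair pathway, genic status,
    transcriptional activity) and a Pearson correlation of induction
    against transcriptional activity.  Produces metagene curves,
    activity-ordered heatmap matrices and paired browser-style coverage
    tracks, and includes a Poisson read simulator of the underlying
    biological model (transcription-coupled canonical R-loops, broad
    transcriptional shutdown around breaks, a sharp damage-induced peak at
    the cut) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    ggplot2,
    yaml,
    methods,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    zoo,
    optparse
Config/testthat/edition: 3
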