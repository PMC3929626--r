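Package: psiscreen
Title: Exon-Array Differential Splicing Screen with PSI Ratios and AGAA
    Motif Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end screen for Tra2b-dependent cassette exons on
    Affymetrix-style exon arrays. Provides probe-level preprocessing
    (RMA-style background correction, optional GC-bin centering, quantile
    normalization, mean/log2 probeset summarization, low-expression
    filtering), transcript-level differential expression by empirical-Bayes
    moderated t statistics, exon-level percent-splicing-inclusion (PSI)
    ratio screening with the 0.66-1.5 exclusion window, exclusion of exons
    on differentially expressed transcripts, AGAA binding-site counting and
    the 256-bp-calibrated binding-site frequency F, premature-termination-
    codon and nonsense-mediated-decay prediction for exon skipping, the
    quantification conventions of isoform validation experiments, and a
    seeded synthetic-data generator with planted expression and splicing
    effects plus Cre-mosaicism dilution for benchmarking the screen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    withr,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
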