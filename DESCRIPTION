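Package: lncstress
Title: Discovery and Stress Co-Expression Analysis of TE-Derived Long
    Non-Coding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-native pipeline for discovering long non-coding RNAs
    (lncRNAs) from mixed polyA+/total-RNA transcript sets, classifying
    transposable-element-derived lncRNAs by superfamily, calling
    stress-responsive transcripts with a negative-binomial Wald test,
    inferring weighted co-expression modules via topological overlap, and
    identifying lncRNA hub transcripts. Includes a deterministic synthetic
    genome/expression generator with planted ground truth so every stage is
    testable at desk scale, plus cis-correlation, expression-entropy,
    Fisher-enrichment and delta-delta-Ct utilities.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    DESeq2,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
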