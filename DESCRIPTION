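Package: tfmirnet
Title: Transcription-Factor to miRNA to Target Regulatory Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative reconstruction of transcription-factor-rooted
    miRNA regulatory networks from promoter annotation, ChIP-seq peak
    calls, and two-condition expression contrasts. Builds promoter
    windows around transcript and pri-miRNA transcription start sites,
    assigns binding peaks under score and overlap thresholds, annotates
    histone marks and binding motifs, applies expression filters and
    differential-expression classification, and selects miRNA-target
    edges by a sign-opposition (anti-correlation) rule to assemble two
    exportable regulatory networks. Includes a synthetic-study generator
    with a planted ground-truth network for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    limma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr
Config/testthat/edition: 3
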