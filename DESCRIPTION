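Package: nascentarch
Title: Nascent Transcription Architecture from csRNA-seq and ATAC-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies and scores the regulatory architecture of nascent
    transcription initiation from strand-specific csRNA-seq read-start tracks
    and ATAC-seq accessible chromatin regions. Provides TSS peak annotation
    against a gene model (summit, 80 percent width, category labels), TMM/CPM
    normalization, antisense TSS detection with proximal/distal classification,
    bidirectional and divergent promoter pairing, transcribed enhancer
    compilation with activity scoring and correlation-based gene linking
    against an inter-chromosomal null, and exosome-sensitivity calls from
    mutant differential tables. A synthetic-data generator plants each feature
    class in a toy multi-chromosome genome with ground-truth tables so the
    whole pipeline can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    edgeR,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
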