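Package: crcscan
Title: Super-Enhancer Calling and Core Regulatory Circuitry Inference
    from H3K27ac Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies super-enhancers from H3K27ac peak and signal data
    by ROSE-style stitching and hockey-stick ranking, assigns them to
    transcription factor genes, scans extended super-enhancer sequences
    with position weight matrices using exact dynamic-programming
    p-values, detects autoregulated transcription factors, enumerates all
    fully interconnected autoregulatory circuitries and scores them by
    occurrence frequency. Ships a synthetic epigenome generator that
    plants a known circuit so every stage of the pipeline can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    igraph,
    jsonlite,
    stats,
    utils,
    methods,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
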