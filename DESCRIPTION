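Package: featsig
Title: Mutation Signature Extraction with Independent Mutation Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models somatic mutation signatures as products of independent
    multinomial distributions over mutation features (substitution type,
    flanking bases, transcription strand), a mixed-membership model fitted
    by an EM algorithm with an optional fixed background signature derived
    from sequence composition. Provides feature extraction from mutation
    position files against a reference sequence, bootstrap standard errors,
    model-selection diagnostics, signature comparison and merging, a
    generative simulator for parameter-recovery and down-sampling
    experiments, and sequence-logo style signature visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ggplot2,
    rlang,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
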