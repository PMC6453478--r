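Package: dogcatchr
Title: Strand-Aware Discovery and Enrichment Analysis of Read-Through
    Transcription Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: De-novo, strand-aware discovery of read-through transcription
    regions flanking annotated genes from stranded RNA-seq coverage.
    Calls downstream-of-gene (DoG) transcripts together with their
    antisense and upstream counterparts (ADoG, PoG, APoG) with a sliding
    window scan over per-strand bedGraph coverage, applies operon and
    cross-category overlap filtering, and quantifies differential
    enrichment in IP-versus-input designs with a negative binomial
    likelihood ratio test on the condition-by-fraction interaction,
    including rRNA-subtraction-ratio size factors and padded
    normalization against annotated genes.  Ships a deterministic
    synthetic-data generator with planted read-through regions and
    planted enrichment for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    withr,
    yaml,
    rtracklayer,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
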