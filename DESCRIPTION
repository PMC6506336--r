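Package: sigscreen
Title: Screening Mutagen-Treated Subclones for Mutational Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterizes mutagen-induced mutational signatures
    from treated versus control single-cell-derived subclones. Provides
    catalog ingestion and filtering (VAF threshold, shared-mutation removal),
    classification of substitutions, double substitutions and indels into
    96-, 78- and 29-channel schemes, bootstrap tests of mutation burden,
    background-subtraction signature extraction with signal-to-noise and
    stability gating, a sequential null model for chance adjacent double
    substitutions, cosine-similarity comparison and clustering of signatures,
    and genome-topography analyses (transcriptional strand asymmetry,
    replication-timing distribution, CpG enrichment). A synthetic-data
    generator produces toy genomes, annotation tracks and subclone mutation
    catalogs with known injected signatures so the full pipeline can be
    exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    ape,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
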