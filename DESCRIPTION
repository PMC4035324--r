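Package: tagdge
Title: Tag-Based Digital Gene Expression Profiling of Staged Tissue Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for 3'-tag digital gene expression (DGE)
    profiling of the SAGE/NlaIII-MmeI type, built around a four-stage
    mushroom stipe development design. Constructs an in-silico reference of
    CATG-anchored 17 bp tags from a gene catalog, cleans raw tag reads into
    per-library count tables, maps clean tags with at most one mismatch while
    excluding ambiguous assignments, normalizes to transcripts per million
    clean tags (TPM), screens differentially expressed genes between
    successive stages with an exact two-library count test and
    Benjamini-Hochberg FDR control, bins fold changes into classes, partitions
    expressed genes across the four stages, aggregates functional categories,
    and verifies expression ratios with the 2^-ddCt method. A seeded
    synthetic-data generator with designed fold-change classes makes the whole
    pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
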