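Package: strucTE
Title: Structure-Based Mining of Transposable Elements and Repeat-Library Curation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure-based detection of complete transposable elements in
    genome assemblies, together with repeat-library curation utilities and a
    synthetic-genome benchmark generator. Implements two-step Helitron mining
    (stringent hairpin/CTRRT terminus discovery followed by relaxed
    genome-wide 40 bp end pairing), Mutator-like element (MULE) detection from
    terminal-inverted-repeat libraries with length-dependent target-site
    duplication validation, miniature inverted-repeat element (MITE) discovery
    under Stowaway and Tourist structural rules with two-round consensus
    building, redundancy clustering and family definition for repeat
    libraries, an extensible Wicker-style classification-code registry with a
    sequence-header codec, and a simulator that plants structurally correct
    elements with ground-truth annotations for recall/precision scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
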