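Package: mirStem
Title: Small RNA Sequencing Analysis with Hairpin-Based miRNA Discovery
    and Two-Library Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing toolkit for two-condition
    (two-library) experiments. Classifies raw reads into removal
    categories (adapter artifacts, short fragments, poly(A)), collapses
    them to unique tags, filters non-coding RNA contaminants, assigns
    tags to known miRNA families with mismatch tolerance, discovers
    novel miRNAs by excising and folding candidate hairpin precursors
    under explicit stem-loop criteria (duplex overlap, bulge count,
    minimum free energy, miRNA* support), calls differentially expressed
    miRNAs between the two libraries with the Audic-Claverie exact count
    test, and scores plant miRNA target sites with a complementarity
    expectation penalty. A seeded synthetic-data generator plants
    hairpins, known families, contaminants and true fold changes so the
    whole pipeline can be validated against a known truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    S4Vectors,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
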