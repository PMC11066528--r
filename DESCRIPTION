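Package: dnarescue
Title: Data Recovery for Fountain-Code-Based DNA Storage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Encoding, decoding and forensic recovery of digital files stored
    in DNA with seeded fountain codes over GF(2). Implements a seeded
    fountain codec with DNA synthesis-constraint screening and a parametric
    substitution/dropout channel, bit-exact Gaussian elimination with
    contribution tracking, automatic detection, localization and repair of
    corrupted packets via equation-system inconsistencies and row
    permutations, file-type-specific error-matrix analyzers (plain text, BMP
    images, ZIP archives), manual missing-row recovery, and applicability
    analyses (packet criticality versus overhead, tagging requirements,
    information density).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
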