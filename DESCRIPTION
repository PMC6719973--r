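Package: agrescreen
Title: In Silico Screening of MHC Class II Agretope Peptides with an
    Empirical Binding Score
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Positional-scanning design of MHC class II binding peptides on a
    rigid peptide-receptor complex. The bound template peptide is reduced to a
    poly-glycine scaffold with its main-chain geometry preserved; candidate
    side chains are rebuilt on the fixed backbone from ideal internal geometry
    over a discrete rotamer grid and scored against the receptor pocket with a
    five-term LUDI-style empirical binding free-energy function (polar, apolar,
    desolvation, flexibility terms plus a constant). A two-stage screen first
    ranks single substitutions per position against the glycine baseline, then
    exhaustively enumerates and ranks the combinatorial library of selected
    per-position candidates. A seeded synthetic-complex generator plants
    analytically known interaction sites so the whole pipeline is testable
    without structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
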