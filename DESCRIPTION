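Package: sh3ags
Title: Sequence, Structure and Binding Analysis of High-Affinity
    SH3/Proline-Rich-Motif Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the high-affinity recognition mode between SH3
    domains carrying a Cxx(D/E) RT-loop signature (the ASAP/GRAF/SKAP or "AGS"
    group) and atypical class-II proline-rich motifs with a positive residue
    inside the PxxP core (xPx+Px+). Provides position-registered proline-rich
    motif scanners, alignment-based RT-loop diagnostic classification of SH3
    domains, a rule-based qualitative affinity predictor reproducing the
    published mutational panel, a proteome-wide candidate screen with a
    localization / polyproline-II / conservation filter cascade and
    hypergeometric term-enrichment statistics, protein-peptide interface
    geometry analysis (contacts, salt bridges, backbone dihedrals, structural
    register assignment), a one-site isothermal titration calorimetry forward
    model and fitter, and synthetic-data generators with ground-truth tables
    so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    igraph,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
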