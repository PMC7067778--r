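Package: cyclometab
Title: Metabolomic-Guided Discovery of Cyclic Nonribosomal Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An untargeted LC-MS metabolomics workflow for prioritizing
    discriminant features and annotating cyclic nonribosomal pentapeptides.
    Implements feature-table filtering (isotope flags, integrated-area and
    retention-time thresholds) and pareto scaling; a from-scratch two-class
    OPLS-DA with cross-validated Q2, VIP scores, S-plot coordinates and the
    parallel include/exclude-top-VIP subset validation; accurate-mass
    dereplication against a bundled compound library via molecular-formula
    parsing, monoisotopic masses, adduct m/z and ppm errors; and a cyclic
    peptide model generating ring-opening b-ion ladders, full cyclospectra,
    MS/MS annotation and leaderboard de novo sequencing. A seeded synthetic
    study generator emulates the two-media, two-host fungal endophyte design
    so every stage is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    jsonlite,
    withr
Config/testthat/edition: 3
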