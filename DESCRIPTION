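Package: degronscan
Title: Degron Discovery from FACS-Seq Protein Stability Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis stack for quality-control degron discovery from pooled
    GPS (global protein stability) reporter screens. Computes Protein
    Stability Index (PSI) scores from per-gate sequencing read counts of a
    tiled peptide library, trains a composition-based logistic regression
    degron predictor (one parameter per amino acid), scans whole proteins
    for degron regions, intersects per-residue degron probabilities with
    transmembrane-segment annotations, runs the multi-strain E3-ligase
    knockout delta-PSI stabilization analysis, and ships a generative
    simulator of the FACS sort-and-sequence screen for offline validation
    and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
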