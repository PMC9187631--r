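Package: pepscreen
Title: Similarity-Based Virtual Screening of Therapeutic Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-silico screening of therapeutic peptide candidates with a
    similarity-based protein-protein interaction scorer. Scores a peptide
    against every protein in a restricted proteome (e.g. a surfaceome) by
    accumulating substitution-matrix-weighted regions of local similarity to
    known interacting pairs, builds one-to-all rank curves with elbow
    detection and morphology classification, performs glycine mutational
    scans, and constructs leakage-controlled optimistic and pessimistic
    evidence scenarios via local-alignment hit removal. Ships a seeded
    synthetic-interactome benchmark generator with a planted
    ligand-receptor interaction so the whole pipeline is testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
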