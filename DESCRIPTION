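Package: trtargets
Title: Thyroid Hormone Receptor Subtype Target-Gene Regulation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for dissecting gene regulation by the two
    thyroid hormone receptor subtypes (TRalpha, TRbeta) over-expressed in
    cultured cell backgrounds. Implements factorial differential expression
    with empirical-Bayes variance moderation separating unliganded-receptor
    effects from ligand (T3) interaction effects, nearest-archetype
    classification of regulation patterns by clamped Euclidean distance,
    cycloheximide-based direct-target calling via the persistence criterion,
    subtype concordance and kinetic-class analytics, and Hill-equation EC50
    estimation with bootstrap intervals. Ships a synthetic-data generator
    emulating the factorial time-course, cycloheximide and dose-series
    designs with ground-truth labels for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
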