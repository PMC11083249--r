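Package: heterosisPatterns
Title: Inheritance-Mode Classification of Gene Expression in F1 Hybrid Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies per-gene inheritance modes of expression in a
    two-parent/F1 cross design from bulk RNA-seq count matrices. Implements
    candidate-gene filtering, counts-per-million normalization, mid-parent
    value (MPV) testing with Benjamini-Yekutieli correction, five-way
    inheritance-mode classification (additive, enhancing dominance,
    suppressing dominance, over-dominance, under-dominance), pairwise
    differential-expression calling under an FDR and fold-change contract,
    and summary reporting. Includes a negative-binomial simulator of
    three-group (P1/P2/F1) count data with known per-gene inheritance modes
    so the whole pipeline can be validated against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
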