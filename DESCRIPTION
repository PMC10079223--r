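Package: g4scan
Title: Convolutional Prediction of G-Quadruplex Propensity from DNA Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts G4-seq-style mismatch scores, a sequencing-based proxy
    for G-quadruplex folding propensity, for arbitrary DNA sequences using a
    small convolutional neural network trained on per-bin mismatch-score
    tracks. Includes peak calling from predicted score tracks, putative
    quadruplex (PQ) motif detection, windowed genome and probe scanning,
    model-interpretation tools (loop-length scans, mutation maps, integrated
    gradients with a uniform baseline), cross-dataset performance matrices
    with rank-correlation summaries, and a synthetic genome/track simulator
    so the whole pipeline is testable at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    stringr,
    jsonlite,
    optparse
Config/testthat/edition: 3
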