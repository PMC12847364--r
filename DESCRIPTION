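Package: imagerybci
Title: Simulation and Decoding of Multi-Class Motor and Singing Imagery EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying multi-class mental-imagery brain-computer
    interfaces from EEG. Provides a protocol-faithful synthetic session
    generator with a controllable event-related desynchronization signal
    model, BrainVision file input/output, a lightweight preprocessing chain
    (polyphase resampling, average re-reference, epoching, whole-epoch
    baseline correction), filter-bank common spatial patterns with binary
    and joint-diagonalization multiclass variants, minimum-redundancy
    maximum-relevance feature selection, random-forest classification under
    leakage-safe repeated stratified cross-validation, binomial chance-level
    thresholds, permutation significance testing, and analyses of trial-wise
    self-evaluation and imagery-questionnaire data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    ranger,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
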