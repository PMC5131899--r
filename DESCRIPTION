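Package: plvnet
Title: Phase-Locking Connectivity, Classification and Partial Least
    Squares for Resting-State MEG Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for frequency-resolved phase-synchronization analysis of
    source-level neurophysiological recordings. Computes phase-locking values
    from constant-Q complex Morlet wavelet decompositions over a logarithmic
    frequency grid, builds subjects-by-frequencies-by-pairs connectivity
    tensors, classifies subjects with nested leave-one-out cross-validated
    linear support vector machines (ROC-area feature ranking, label-shuffle
    permutation nulls, decision-boundary confidence), and tests group and
    behavioural effects with mean-centred and behavioural partial least
    squares (permutation tests, bootstrap ratios, tail-count profiles,
    two-sample proportion z-tests). Includes a coupled-oscillator cohort
    simulator with planted frequency-specific effects so the full pipeline is
    testable without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    withr,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
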