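Package: msbold
Title: EEG Microstate Dynamics and BOLD fMRI Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline linking EEG microstate dynamics to
    simultaneous BOLD fMRI. Implements microstate template extraction
    (global field power peaks, atomize-and-agglomerate hierarchical
    clustering, group template alignment), winner-take-all backfitting,
    three microstate-derived regressor families (direct time course,
    switching activity, pairwise transitions) convolved with a canonical
    double-gamma hemodynamic response function, subject- and group-level
    general linear models with sign-flip permutation cluster-extent
    correction and network-overlap summaries, and a multi-output
    time-delay neural network for bidirectional microstate/BOLD
    prediction with expanding-window time-series cross-validation.
    Ships a synthetic simultaneous EEG-fMRI generator with known ground
    truth so every stage is testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
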