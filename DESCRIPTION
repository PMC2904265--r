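Package: spellerbci
Title: Simulation and Offline Decoding of ERP-Based Visual Speller
    Brain-Computer Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying event-related-potential (ERP) based visual
    spellers of the oddball type. Builds Matrix and two-level Hex-o-Spell
    layouts, generates constrained pseudo-random intensification schedules,
    synthesizes continuous 64-channel EEG with overlapping evoked components
    and colored background noise, extracts and filters stimulus-locked
    epochs, measures ERP components (P1, N1, P2, N2, P3) with peak picking
    and mean-amplitude fallback, and performs single-trial target versus
    nontarget classification with shrinkage-regularized linear discriminant
    analysis followed by two-stage symbol decoding, accuracy-versus-sequences
    curves, and spatial/temporal discriminability maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
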