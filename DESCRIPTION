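Package: axonflux
Title: Directional Axonal Connectivity Analysis for Organoid Microchannel
    Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for action-potential propagation and firing-rate
    asymmetry in microchannel recordings between neural organoids on
    high-density microelectrode arrays. Detects extracellular spikes with an
    RMS-multiple threshold and refractory filtering, reconstructs propagation
    paths along a channel's principal axis with intermediary electrodes and
    least-squares conduction-velocity fits, computes quartile firing rates and
    entry/exit flux-ratio asymmetry statistics, and quantifies neurite
    outgrowth from growth-cone tracks and axial fluorescence profiles. A
    synthetic-data module simulates Poisson-firing axon populations, injected
    propagating events, raw trace rendering, and neurite tracks so the whole
    pipeline is testable without recordings.
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
    jsonlite,
    purrr,
    rhdf5,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    multcomp,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
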