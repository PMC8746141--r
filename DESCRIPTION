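Package: braidr
Title: Braid Diagrams and Braid Surfaces for Staging on Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates prion-like protein propagation on weighted structural
    brain networks with a network Fisher-KPP seed model coupled to a
    neurofibrillary-tangle accumulation equation, and characterizes the
    resulting regional staging patterns. Provides the parametrized
    graph-Laplacian family with mass-conservation and Fick's-condition audits,
    length-free/ballistic/diffusive edge weightings, naive and disparity-filter
    backbone thresholding, threshold-crossing-time tables, staging-pattern
    classification, and braid diagrams and braid surfaces with a
    discovery-order pattern registry.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
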