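Package: panlink
Title: Protected-Area Network Connectivity: Resistance Surfaces, Corridors,
    Circuit Theory and Conservation-Target Accounting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and assesses protected-area networks (PANs) on raster
    landscapes. Derives expert factor weights with the analytic hierarchy
    process (AHP), composes weighted five-level resistance surfaces, maps
    least-cost paths and normalized least-cost corridors between protected-area
    patches, solves circuit-theory current flow to locate pinch points,
    scans moving windows for barriers whose restoration would shorten
    least-cost linkages, prioritizes patches and corridors by current-flow
    centrality, screens candidate sites for other effective area-based
    conservation measures (OECMs), and accounts for coverage against the
    30-percent area target of the Global Biodiversity Framework and SDG 15
    indicators. Includes a seeded synthetic coastal-landscape generator with
    planted corridors and barriers so every stage is testable without
    proprietary GIS layers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    MASS,
    optparse
Config/testthat/edition: 3
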