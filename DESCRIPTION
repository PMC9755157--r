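Package: nightnets
Title: Day and Night Proximity-Based Animal Social Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and contrasts daytime and nighttime animal social
    networks from dyadic proximity-logger records. Raw mirrored encounter
    records are deduplicated, discretized into 5-minute proximity events,
    labelled by phase (day/night) and social context (active/passive), and
    aggregated into simple-ratio-index association networks per period.
    Overlapping link communities define social groups and the strata of
    focal data-stream permutations, which provide permutation p-values for
    network-trait contrasts between consecutive days and nights, cosine
    similarity comparisons across contexts and across periods, and an
    empirical Fisher combination of dependent p-values. A synthetic
    proximity-logger generator with known ground truth (group structure,
    day/night encounter rates, duration mixture, nighttime partner
    selectivity) makes the full pipeline testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
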