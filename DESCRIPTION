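Package: aopnet
Title: Derivation and Topological Analysis of Adverse Outcome Pathway Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Merges curated linear adverse outcome pathways (AOPs) into a single
    directed network of key events (KEs) and key event relationships (KERs) and
    computes the node-level statistics used to identify the most central key
    events: in/out/total degree with convergence and divergence classification,
    directed eccentricity with upstream/middle/downstream banding, normalised
    betweenness centrality, the normalised MIE-to-AO simple-path occurrence
    score (cycle-safe), AOP-sharing counts, and the weight-of-evidence
    distribution over relationships. Includes a reader and validator for
    AOP-Wiki-style curated relationship tables, key-event title harmonisation,
    a seeded generator of synthetic AOP collections for testing, and
    Cytoscape-interoperable GraphML/SIF exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stringi,
    tibble
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
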