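Package: ecnet
Title: Extended Core Gene Networks and Sense/Anti-Sense Differential Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers extended core gene co-expression networks from
    mutual information estimated on copula-transformed expression data,
    generalising the single-best-edge core network to an accepting-rate
    neighbourhood with an asymmetric adjacency matrix. Provides the
    differential network analysis of sense versus sense-plus-anti-sense
    transcriptomic data built on these networks: anti-sense-impacted genes,
    change motifs, AS-impacted sub-graphs and their Steiner-tree rewiring,
    together with hypergeometric GO/GO-slim enrichment and a synthetic
    regulatory-network benchmark with precision/recall/F1 evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
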