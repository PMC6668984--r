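Package: gbsnet
Title: Immune and Disease Gene Co-Expression Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs protein-protein-interaction-constrained gene
    co-expression networks from two-group expression profiles, classifies
    network genes by immune and disease annotation, mines dense network
    modules, classifies samples by Monti-style resampling consensus
    clustering with CDF/delta-AUC model selection, and computes
    differential-expression and hypergeometric over-representation
    statistics. Includes a synthetic-data generator with planted
    co-expression modules, a scale-free PPI overlay and annotated gene
    sets, so the full analysis is reproducible without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
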