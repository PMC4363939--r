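Package: plsig
Title: Early Gene-Expression Signatures of Metabolic Disease via
    Partial Least Squares
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links early tissue gene-expression measurements to late
    physiological outcomes (body weight, blood glucose, cytokine panels)
    in diet-induced obesity studies. Provides microarray replicate-
    consistency filtering and probe deduplication into per-week master
    lists, a NIPALS partial least squares engine tolerant of missing
    values with cross-validated Q2 diagnostics and VIP-based gene
    selection, signature training with intersection/union week
    protocols, a linear cross-experiment conversion with reference-range
    effectiveness classification, and interaction-network
    characterization (power-law degree fit, module connectivity
    statistics, hub extraction). A synthetic study generator with
    planted linear signal makes every stage testable without the
    original arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
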