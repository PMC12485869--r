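Package: ccmkit
Title: Quantifying Ligand-Induced Collective Cell Migration and Network Rewiring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify collective cell migration phenotypes from
    live-cell tracking tables (normalized cell count, mean-squared-displacement
    motility, Clark-Evans-style nearest-neighbor clustering index, and a
    velocity cosine-similarity order parameter), together with screen-level
    statistics (control normalization, Dunnett many-to-one tests, phenotype
    PCA, exact binomial effect enrichment) and a comparative-network module
    that scores per-node rewiring between two condition networks and nominates
    candidate regulators weighted by log-fold change. A synthetic-data module
    generates tracks, spatial point patterns, phenotype tables and paired
    condition networks with known ground truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    multcomp,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
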