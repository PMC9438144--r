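Package: mirtarnet
Title: Differential miRNA Expression and Signed miRNA-Target Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Differential expression analysis of PBMC miRNA count data with
    trimmed-mean-of-M-values normalization, precision-weighted moderated
    t-statistics and average-rank prioritization; construction of a signed
    bipartite miRNA-target network whose per-gene node strengths predict the
    direction of target expression change; validation of those predictions
    against measured mRNA log2 fold changes; and frequency-filtered
    hypergeometric overrepresentation analysis. Includes a negative-binomial
    synthetic-data generator with planted effects so the whole pipeline is
    testable without external data, plus readers and writers for counts,
    design, interaction-database, GMT and network (SIF/GraphML) files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
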