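Package: clustershift
Title: Temporal Cluster-Transition Analysis for Perturbed Time-Course RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects treatment-induced shifts in temporal gene-expression
    programs from short time-course bulk RNA-seq designs. Counts are TMM
    normalized to log2-TPM, genes are tested with empirical-Bayes moderated
    t-statistics over a cell-means design, dynamic genes are clustered by
    fuzzy c-means on merged control/treatment temporal profiles, and
    control-to-treatment cluster-transition matrices identify genes whose
    temporal program is re-timed by the perturbation. Includes preranked
    gene-set enrichment with signed log-p ranking, hypergeometric
    over-representation analysis, enrichment-map export, signature-based
    cell-type abundance scoring, and a negative-binomial synthetic-data
    generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    limma,
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
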