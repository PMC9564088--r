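Package: bcrnet
Title: Clonal Network and Diversity Analysis of B Cell Receptor Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds clonal networks from B cell receptor (BCR) CDR3 nucleotide
    sequences (vertices are unique sequences, edges join single-nucleotide
    neighbours, clones are connected components), computes clone- and
    cluster-level diversity indices (Shannon, Gini-Simpson, Gini) normalized to
    a healthy cohort, tracks primary tumor clones in peripheral repertoires by
    Levenshtein distance for minimal residual disease (MRD) calling, and
    discriminates relapse from non-relapse trajectories with ROC analysis of
    the post-transplant diversity recovery (delta-SDI). Includes a germinal
    center co-culture simulator with an optional non-mutating tumor compartment
    and a patient-timeline generator for high-dose therapy with autologous stem
    cell rescue (HDT-ASCR) cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
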