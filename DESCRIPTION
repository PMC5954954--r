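Package: netpharm
Title: Network Pharmacology Analysis of Compound-Target and Protein
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for network-pharmacology studies of
    multi-compound medicines (for example herbal preparations) against a
    disease gene set. It assembles disease targets from multiple evidence
    sources, builds compound-target bipartite networks and scored
    protein-protein interaction (PPI) networks in the STRING download
    dialect, intersects PPI expansions of compound and disease targets,
    screens hub proteins by median degree, betweenness and closeness,
    detects dense molecular complexes with a from-scratch implementation of
    the MCODE algorithm, and tests module gene sets for functional
    over-representation with exact hypergeometric tails and
    Benjamini-Hochberg false-discovery-rate control. A synthetic-data
    generator with known ground truth (planted PPI modules, enriched
    annotation terms, overlapping disease sources) makes every stage of the
    pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
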