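Package: phytonet
Title: Network Pharmacology Inference for Multi-Compound Herbal Preparations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the network-pharmacology workflow that links the
    chemical constituents of a multi-compound preparation to candidate
    disease mechanisms. Covers quadrupole time-of-flight peak annotation
    (monoisotopic mass, adduct m/z, ppm error, bounded candidate-formula
    enumeration with a rings-plus-double-bonds filter), screening and
    merging of compound-target predictions and multi-source disease gene
    lists, bipartite compound-target network construction with degree and
    Brandes betweenness screening of main ingredients, protein-protein
    interaction filtering by combined score with hub-gene ranking,
    hypergeometric over-representation analysis, and assembly of the
    compound-target-pathway network. Includes a seedable synthetic-study
    generator with planted ground truth and a single-command pipeline.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
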