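Package: viropop
Title: Population Structure, Coinfection and Reassortment Analysis for
    Segmented Viruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise the population structure of segmented
    RNA viruses from per-segment nucleotide alignments and sample
    metadata: pairwise identity and Tamura-Nei (TN93) distances,
    neighbour-joining trees with midpoint rooting and short-branch
    collapse, identity-plus-monophyly genotype assignment, coinfection
    profiling, Hudson's nearest-neighbour statistic (Snn) with
    permutation tests for geographic structure, identity-gap detection of
    reassortment across segment cophylogenies, and the supporting
    statistical layer (delta-Ct quantification, exact binomial intervals,
    Fisher/Holm, Wilcoxon, bootstrap t tests, RPM normalisation). A
    seeded synthetic-data generator produces datasets with known clade,
    coinfection, reassortment and geographic ground truth so every stage
    of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
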