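Package: deepsage
Title: Digital Gene Expression Analysis for SuperSAGE Tag Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A complete desk-scale workflow for deepSuperSAGE digital gene
    expression profiling: extraction of anchored 26 bp tags from ditag reads,
    per-library UniTag counting and filtering, normalization to copies per
    100,000 tags, exact Audic-Claverie significance testing of count
    differences between libraries, detection of SNP-associated alternative
    tag (SAAT) families by fixed-length sequence identity clustering,
    EST-bridged tiered protein and GO annotation transfer, gene score
    resampling (GSR) over-representation analysis of GO and custom
    categories, and a ground-truthed synthetic data generator that emulates
    the structure of a two-organ, two-condition salt-stress experiment so
    every step of the pipeline can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
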