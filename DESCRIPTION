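Package: ecmatlas
Title: Regional Extracellular Matrix Expression and Deposition Analytics
    for Mouse Hair Follicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for mapping basement-membrane and interstitial
    extracellular matrix (ECM) specialization across mouse hair follicle
    compartments from sorted-population RNA-seq and regional
    immunofluorescence. Provides a curated matrisome catalogue partitioned
    into basement-membrane and interstitial divisions, median-of-ratios
    count normalization, negative-binomial differential expression (Wald
    and likelihood-ratio tests) with epithelial-versus-dermal origin
    calling, gene-set-restricted Spearman correlation profiling,
    region-specific ECM program discovery (dendrogram cut plus two-means
    region labeling), permutation gene-set enrichment, six-zone protein
    deposition quantification with mRNA-protein concordance
    classification, morphometry helpers, a ground-truth synthetic data
    generator, and a reproducible end-to-end pipeline.
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
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
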