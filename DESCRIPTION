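Package: pmindex
Title: Gut Microbiome Dysbiosis Analysis and the Psoriasis-Microbiome Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genus-level analysis of 16S gut microbiome cohorts with a focus
    on psoriasis-associated dysbiosis. Provides abundance-table handling with
    Greengenes-style taxonomy, low-confidence taxon filtering, alpha diversity
    (Chao1, rarefaction), phylogenetic beta diversity (unweighted and weighted
    UniFrac) with PCoA and PERMANOVA, LEfSe-style differential genus selection
    by Kruskal-Wallis screening and bootstrapped linear-discriminant effect
    sizes, the Firmicutes:Bacteroidetes ratio, and the Psoriasis-Microbiome
    Index (PMI): a log-ratio dysbiosis score with ROC cutoff calibration,
    stratified tenfold cross-validation and frozen-index application to
    independent cohorts. A Dirichlet-multinomial cohort simulator generates
    realistic two-group study data for testing and benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    MASS,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    picante,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
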