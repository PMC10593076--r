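Package: mvimpute
Title: Cross-Omics Imputation of Metabolite Abundances with a Multi-View
    Variational Autoencoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Imputes missing metabolite abundances from whole-genome
    genotype data and a small set of fully observed template metabolites.
    Genome-wide variation is encoded as three per-subject feature views
    (template-derived rare-variant burden scores, polygenic scores, and
    LD-pruned common SNPs), fused with a product-of-experts multi-view
    variational autoencoder, and decoded into a per-metabolite prediction.
    Includes the supporting genetics feature engineering (Hardy-Weinberg
    exact-test QC, MAF partitioning, windowed LD pruning, polygenic
    scoring, genetic principal components), within-omics baseline
    regressors, evaluation metrics with threshold summaries, and a
    seeded synthetic-data generator emulating a heritable metabolite
    cohort so the full pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR
Config/testthat/edition: 3
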