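Package: paincell
Title: Linking Single-Cell DRG Expression to Chronic-Pain Heritability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline connecting single-cell dorsal root ganglion
    (DRG) transcriptomes to gene-level GWAS statistics for chronic pain.
    Provides median-of-ratios size factors, per-gene cluster-specificity
    regression with top-fraction gene-set selection, a probabilistic
    neural-network cell-identity scorer with permutation significance and
    radar embedding, a gene-level cluster-by-GWAS "area" enrichment
    statistic with a product-of-normals (Bessel K0) null, hypergeometric
    pathway overrepresentation, SNP annotation tracks for partitioned
    heritability, fixed-effect meta-analysis of heritability coefficients,
    and a synthetic-data module that emulates every input so the whole
    pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    GenomicRanges,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    metafor,
    fgsea,
    withr
Config/testthat/edition: 3
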