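Package: DimorphScreen
Title: Sex-Dimorphism Analysis of the Drosophila Gut Endocrine Screen
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies sexual dimorphism in the Drosophila midgut endocrine
    system and in multi-assay phenotypic screens of enteroendocrine-cell
    gene knockdowns. Provides synthetic two-channel gut image and screen
    data generators with planted ground truth, geodesic gut-axis tracing
    and nucleus/GFP segmentation, decile-resolved length-scaled enrichment
    statistics with Holm-Sidak adjustment and Welch/Dunnett-T3 group
    comparisons, reducers for survival, metabolite, sleep and feeding
    assays, screen-wide z-score hit calling with sex-specificity Venn
    statistics, Spearman average-linkage clustering, and centered-SVD PCA
    with phenotypic-space distances to opposite-sex references.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    Rcpp,
    jsonlite,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
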