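Package: IPMGfinder
Title: Discovery of Immunotherapy Prognostic Marker Genes from
    Pan-Cancer Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pan-cancer computational pipeline for discovering
    immunotherapy prognostic marker genes (IPMGs) from bulk tumor
    expression, somatic mutation, clinical, immune-fraction and genotype
    data. Implements two expression-correction strategies (a
    trinucleotide-context mutation correction built on codon-level
    dN/dS backgrounds and protein-activity scores, and a leukocyte
    fraction correction for immune-related genes), a stratified
    one-tailed log-rank survival screen, pre-ranked gene set enrichment
    with a resampling-based immunotherapy-specificity test, ssGSEA plus
    random survival forest feature selection, a SMOTE-balanced elastic
    net survival-status classifier, ssGSEA-based patient
    stratification with a resampling control, and permutation-thresholded
    SNP association. Ships a synthetic TCGA-shaped cohort generator with
    planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    GenomicRanges,
    IRanges,
    survival,
    glmnet,
    ranger,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    limma
biocViews: Survival, GeneExpression, SomaticMutation, ImmunoOncology,
    GeneSetEnrichment, Classification
Config/testthat/edition: 3
RoxygenNote: 7.3.3
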