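Package: rnleti
Title: Helper-NLR Dependency Classification of Effector-Triggered
    Immunity Transcriptomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for time-resolved factorial RNA-seq studies
    of plant effector-triggered immunity (ETI) in helper-NLR (RNL) mutant
    panels. Simulates negative-binomial count data with planted PTI/ETI
    effects across a genotype x treatment x time design, performs
    median-of-ratios normalization, method-of-moments dispersion
    estimation and per-contrast negative-binomial Wald tests, calls
    differentially expressed genes at FDR and fold-change thresholds,
    classifies ETI-regulated genes into five RNL-dependency categories
    (RNL-independent, synergistic, redundant, ADR1-specific,
    NRG1-specific) from their differential-expression status across four
    genotypes, and produces fraction-accounting reports, Venn overlap
    counts, hypergeometric term enrichment, and infection-phenotype
    statistics (disease index, sporangiophore binning, cfu conversion,
    ROS totals, ANOVA with Tukey letter displays).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Matrix,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    MASS,
    SummarizedExperiment
Config/testthat/edition: 3
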