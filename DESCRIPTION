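Package: devmqtl
Title: Methylation QTL and Allelic Expression Analysis in Developing and Aged Skeletal Tissue
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A targeted molecular-epigenetics toolkit for methylation
    quantitative trait locus (mQTL) panels in developing and aged skeletal
    tissues. Provides readers and validators for locus/CpG definition
    tables, quality control and beta/M-value transformation of
    pyrosequencing methylation measurements, genotype-stratified mQTL
    regression with genotypic-effect summaries, allelic expression
    imbalance (AEI) analysis with an exact Wilcoxon signed-rank test,
    methylation-expression QTL regression, CpG co-methylation clustering,
    consensus ATAC peak-set algebra with chromatin-state enrichment and
    LD-proxy variant prioritization, and a synthetic-cohort generator that
    reproduces the statistical structure of such studies for closed-loop
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Epigenetics, DNAMethylation, GeneExpression, QualityControl,
    StatisticalMethod, ATACSeq
RoxygenNote: 7.3.3
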