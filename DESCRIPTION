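Package: nedmr
Title: Neuroendocrine Differentially Methylated Regions and Regulatory
    Element Integration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies neuroendocrine-specific differentially methylated
    regions (NE-DMRs) from Illumina-style beta-value matrices by
    Mann-Whitney testing with Bonferroni correction and median-difference
    filtering, merges significant probes through 101 bp windows, links
    regions to transcription start sites within 500 kb and calls
    significant methylation-expression correlations by an empirical
    percentile cutoff.  Derives tissue coexpression gene modules by
    classical multidimensional scaling and k-means, scores tumors for a
    neuroendocrine phenotype with ROC/AUC evaluation, tests ATAC-seq peak
    counts for differential accessibility with a negative-binomial Wald
    test, links peaks to genes proximally and distally by expression
    correlation, and intersects tumor DMRs with accessibility peaks
    through fixed-width consensus windows.  Ships a synthetic-data
    generator with a planted ground-truth manifest so the whole pipeline
    is testable end to end without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
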