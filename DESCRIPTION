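Package: ceRNAprofiler
Title: Ordered-Condition Expression Profiling and ceRNA Network Inference for
    lncRNA Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mining long noncoding RNAs associated with an ordered
    disease progression from bulk expression data. Implements short-series
    model-profile clustering with permutation significance over an ordered
    condition axis (e.g. Sham, PD, NLID, LID), differential-expression and
    Fisher-exact enrichment screens, a rule-based lncRNA candidate filter with
    a built-in open-reading-frame scanner, co-expression and competing
    endogenous RNA (lncRNA-miRNA-mRNA) network inference via percentile
    correlation thresholds and perfect 6mer seed matching, cis and trans
    lncRNA target prediction, and 2^-ddCt relative quantification for qPCR
    validation. A synthetic-data generator with planted ground truth makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    GenomeInfoDb,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    limma,
    rtracklayer,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, Network, Clustering
RoxygenNote: 7.3.3
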