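Package: lncoLink
Title: lncRNA-Related and Coexpressed mRNA Biomarker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery and validation of mRNA biomarkers that are
    positionally related to, and coexpressed with, differentially
    expressed long non-coding RNAs (lncRNAs), as applied to
    hepatocellular carcinoma tumor/normal expression profiling.
    Provides strand-aware positional classification of lncRNA-mRNA
    pairs into six relationship categories (exon sense-overlapping,
    intron sense-overlapping, intronic antisense, natural antisense,
    bidirectional, intergenic), per-feature Box-Cox power
    transformation with Welch two-sample testing and Storey q-value
    false discovery rate control, paired-significance biomarker
    selection, and RBF-kernel SVM validation with stratified
    cross-validation and cross-platform (microarray to RNA-seq)
    blind testing. A synthetic-data module generates transcript
    geometries and expression studies with known ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    rtracklayer,
    GenomicRanges,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
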