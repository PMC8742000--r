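Package: medseqr
Title: Differential Methylation Analysis for Methylation-Dependent
    Restriction Enzyme Sequencing (MeD-seq)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for differential-methylation analysis of
    methylation-dependent restriction enzyme (LpnPI) digest sequencing:
    simulation of digest fragments and per-site count matrices with planted
    differentially methylated regions (DMRs), recognition-site cataloguing
    and promoter/gene-body/CpG-island annotation, adapter trimming and the
    13-17 bp restriction-site position filter, chi-squared sliding-window
    DMR detection with Bonferroni or Benjamini-Hochberg correction,
    one-vs-rest group-unique DMR calling, directional integration of DMRs
    with differential gene expression, and RPM/Z-score normalisation with
    complete-linkage cityblock hierarchical clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    BiocGenerics,
    methods,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    rtracklayer,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
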