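Package: tfbsflow
Title: Promoter TFBS Enrichment and Expression Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for transcription-factor
    binding-site (TFBS) enrichment analysis of differentially expressed
    genes. Parses TRANSFAC-format position weight matrices, scans
    strand-aware 1 kb upstream promoter sequences with min-max relative
    score thresholding, and tests per-factor over-representation of
    motif-bearing genes among up-regulated genes with a hypergeometric
    test and Benjamini-Hochberg correction. Companion expression stages
    provide FPKM quantification, median-of-ratios normalisation, a
    calibrated differential-expression test for NB counts,
    fold-change/adjusted-p classification, average-linkage clustering on
    Pearson correlation distance, qPCR 2^-ddCt fold changes and
    cross-platform correlation. A synthetic-data module generates
    ground-truth-bearing genomes, promoters with planted motifs and
    negative-binomial count matrices so the whole pipeline is testable
    end to end without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    ape,
    yaml,
    jsonlite,
    limma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
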