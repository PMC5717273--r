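Package: methylscan
Title: Sliding-Window Comparison of Sparse Invertebrate Methylomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares two whole-genome bisulfite sequencing (WGBS)
    methylomes of the sparse, CpG-dominant kind found in insects. Provides
    per-cytosine report input/output, binomial methylation-site calling
    with lambda spike-in non-conversion correction, genome-wide context
    statistics, a sliding-window methylation landscape, a sliding-window
    differentially-methylated-region caller based on Fisher's exact test
    with dual effect-size filters, false discovery rate control and
    iterative merge-and-retest, gene-component annotation of the resulting
    regions, metagene methylation profiles, flanking k-mer preference
    analysis, and a synthetic methylome generator with planted
    differential regions and ground truth for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
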