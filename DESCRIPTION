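Package: mascseq
Title: Processing and Analysis of Spatially Barcoded Microarray Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end processing of microarrayed single-cell RNA sequencing
    (MASC-seq style) experiments, in which cells are imaged on a barcoded
    spot array and paired reads carry an 18 nt spot barcode plus a
    semi-randomized 9 nt unique molecular identifier. Provides a kmer-based
    barcode demultiplexer with mismatch correction, UMI deduplication by
    hamming-distance clustering, spot-occupancy annotation from imaged cell
    centroids, QC statistics (saturation curves, dropout rates, CV-vs-rank,
    background-gene filtering), two-species crosstalk estimation,
    normalization (TP200K/TP10K), permutation-based principal component
    significance, hierarchical clustering and t-SNE embedding, a two-part
    likelihood-ratio test for differential expression between clusters, and
    cell-cycle phase scoring. A synthetic-data simulator generates paired
    reads, array layouts and ground truth so that every pipeline stage can
    be verified without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    Rtsne,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
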