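Package: hologwas
Title: Hologenome-Wide Association Studies with Host and Microbiome Kernels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Linear mixed model association scans for complex traits that
    jointly model host genetic and gut microbial variation. Builds genomic
    (GRM), microbial (MRM), and hologenome relationship matrices (a
    Cholesky cross-covariance kernel and a Hadamard product kernel) from
    SNP genotypes and OTU relative abundances, estimates multi-kernel
    variance components by average-information REML, and runs
    eigendecomposition-accelerated per-SNP Wald scans. Includes
    quality-control filters, significance regimes (Bonferroni,
    Benjamini-Hochberg, permutation genome-wide thresholds), genomic
    inflation diagnostics, SNP-to-gene window annotation from GFF3, a
    synthetic hologenome data generator, Manhattan/QQ plots, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    data.table,
    jsonlite,
    yaml,
    ggplot2,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
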