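Package: SweepScan
Title: Selective-Sweep Mapping in Breed-Structured SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection of artificial-selection signatures in multi-breed SNP
    array data. Implements per-SNP Weir-Cockerham differentiation screens with
    region clustering, windowed S_i (relative heterozygosity) and d_i
    (standardized pairwise F_ST) genome scans whose region lengths are tested
    against a coalescent length null with Benjamini-Hochberg FDR control,
    breed-permutation max-T genome-wide association, shared homozygous core /
    identity-by-state haplotype extraction, and cross-population extended
    haplotype homozygosity (XP-EHH) validation. A synthetic-data module
    simulates breed panels under a wolf-domestication-breed-bottleneck
    demographic model with array-ascertainment frequency matching, LD-decay
    based bottleneck fitting, and sweep planting for power studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3), GenomicRanges, SummarizedExperiment
Imports: methods, stats, utils, Matrix, jsonlite, S4Vectors, IRanges,
    BiocGenerics, GenomeInfoDb, vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
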