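#' Sliding windows over a SNP map
#'
#' Tiles every chromosome with `windowBp` windows advancing by `stepBp`,
#' anchored at position 0, and drops windows holding fewer than `minSnps`
#' array loci (counted before any per-breed restriction). The defaults are
#' the 150 kb / 25 kb / 5-SNP scheme used by the sweep scans.
#'
#' @param loci a `GRanges` of SNP positions or a [GenotypePanel-class]
#' @param windowBp window length in bp
#' @param stepBp step between window starts in bp
#' @param minSnps minimum loci for a window to be retained
#' @return `GRanges` of retained windows with metadata columns `n_snps` and
#'   `chromClass`
#' @export
makeWindows <- function(loci, windowBp = 150000L, stepBp = 25000L,
                        minSnps = 5L) {
    if (is(loci, "GenotypePanel")) loci <- rowRanges(loci)
    if (windowBp <= 0L || stepBp <= 0L)
        stop("windowBp and stepBp must be positive")
    pieces <- lapply(split(loci, as.character(seqnames(loci))), function(lc) {
        lastPos <- max(start(lc))
        starts0 <- seq.int(0L, lastPos - 1L, by = stepBp)   # 0-based anchors
        gr <- GRanges(as.character(seqnames(lc))[1L],
                      IRanges(starts0 + 1L, width = windowBp))
        ov <- findOverlaps(gr, lc)
        gr$n_snps <- tabulate(queryHits(ov), length(gr))
        cls <- as.character(mcols(lc)$chromClass)
        first <- cls[subjectHits(ov)][!duplicated(queryHits(ov))]
        gr$chromClass <- NA_character_
        gr$chromClass[unique(queryHits(ov))] <- first
        gr[gr$n_snps >= minSnps]
    })
    ans <- unlist(GRangesList(pieces), use.names = FALSE)
    ans
}

#' SNP membership of windows
#'
#' @param windows `GRanges` from [makeWindows]
#' @param loci `GRanges` of SNP positions (or a panel)
#' @return an [IRanges::IntegerList], locus indices per window
#' @export
windowSnpIndices <- function(windows, loci) {
    if (is(loci, "GenotypePanel")) loci <- rowRanges(loci)
    ov <- findOverlaps(windows, loci)
    S4Vectors::splitAsList(subjectHits(ov),
                           factor(queryHits(ov), seq_along(windows)))
}

# sparse window-membership matrix (windows x loci) for fast window sums
.windowMembership <- function(windows, loci) {
    if (is(loci, "GenotypePanel")) loci <- rowRanges(loci)
    ov <- findOverlaps(windows, loci)
    Matrix::sparseMatrix(i = queryHits(ov), j = subjectHits(ov), x = 1,
                         dims = c(length(windows), length(loci)))
}
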