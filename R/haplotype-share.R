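#' Fully homozygous core regions of a breed within candidate regions
#'
#' Inside each candidate region, finds the maximal runs of consecutive SNPs
#' where the region's breed has no heterozygous call and a single allele
#' among non-missing genotypes ("completely homozygous"). Missing genotypes
#' inside an otherwise fixed run are treated as compatible; the per-core
#' missingness fraction is reported. Phase is not required.
#'
#' @param panel a [GenotypePanel-class]
#' @param regions `GRanges` with a `breed` metadata column (e.g. significant
#'   S_i regions)
#' @return `GRanges` of cores with mcols `breed`, `n_snps`, `missing_frac`
#' @export
homozygousCores <- function(panel, regions) {
    out <- list()
    g <- genotypes(panel)
    br <- breeds(panel)
    rr <- rowRanges(panel)
    for (k in seq_along(regions)) {
        breed <- regions$breed[k]
        snpIdx <- which(as.logical(
            seqnames(rr) == as.character(seqnames(regions[k])) &
            start(rr) >= start(regions[k]) & start(rr) <= end(regions[k])))
        if (length(snpIdx) == 0L) next
        sub <- g[snpIdx, br == breed, drop = FALSE]
        fixed <- apply(sub, 1L, function(x) {
            x <- x[!is.na(x)]
            length(x) == 0L || (all(x != 1L) && length(unique(x)) == 1L)
        })
        runs <- rle(fixed)
        ends <- cumsum(runs$lengths)
        starts <- ends - runs$lengths + 1L
        for (r in which(runs$values)) {
            idx <- snpIdx[starts[r]:ends[r]]
            sub2 <- g[idx, br == breed, drop = FALSE]
            core <- GRanges(seqnames(regions[k]),
                            IRanges(start(rr)[idx[1L]],
                                    start(rr)[idx[length(idx)]]))
            core$breed <- breed
            core$n_snps <- length(idx)
            core$missing_frac <- mean(is.na(sub2))
            out[[length(out) + 1L]] <- core
        }
    }
    if (length(out) == 0L)
        return(GRanges(breed = character(), n_snps = integer(),
                       missing_frac = numeric()))
    unlist(GRangesList(out), use.names = FALSE)
}

#' Cluster homozygous cores across breeds by physical overlap
#'
#' Single-linkage clustering: cores sharing at least 1 bp, directly or
#' through a chain of overlaps, join one cluster.
#'
#' @param cores `GRanges` from [homozygousCores]
#' @return `cores` with an integer `cluster` metadata column
#' @export
clusterCores <- function(cores) {
    if (length(cores) == 0L) { cores$cluster <- integer(); return(cores) }
    comp <- reduce(granges(cores), min.gapwidth = 0L)
    ov <- findOverlaps(granges(cores), comp)
    cores$cluster <- subjectHits(ov)
    cores
}

#' Maximal shared identical-haplotype interval of a cluster
#'
#' Within the region jointly covered by all cluster cores, finds the
#' longest run of consecutive SNPs at which every breed of the cluster is
#' fixed for the same allele (identity by state). Returns `NULL` when the
#' cluster spans fewer than two breeds, the cores do not jointly overlap,
#' or no SNP carries one shared fixed allele.
#'
#' @param cores `GRanges` of one cluster (same chromosome)
#' @param panel the [GenotypePanel-class]
#' @return `GRanges` of one interval with mcols `breeds`, `n_breeds`,
#'   `n_snps`, or `NULL`
#' @export
maximalIbs <- function(cores, panel) {
    ub <- unique(cores$breed)
    if (length(ub) < 2L) return(NULL)
    lo <- max(start(cores)); hi <- min(end(cores))
    if (lo > hi) return(NULL)
    rr <- rowRanges(panel)
    chr <- as.character(seqnames(cores))[1L]
    snpIdx <- which(as.logical(seqnames(rr) == chr) & start(rr) >= lo &
                    start(rr) <= hi)
    if (length(snpIdx) == 0L) return(NULL)
    g <- genotypes(panel)
    br <- breeds(panel)
    # fixed dosage (0 or 2) per breed per SNP, NA when polymorphic/het
    fixedAllele <- vapply(ub, function(b) {
        sub <- g[snpIdx, br == b, drop = FALSE]
        apply(sub, 1L, function(x) {
            x <- x[!is.na(x)]
            if (length(x) && all(x != 1L) && length(unique(x)) == 1L) x[1L]
            else NA_integer_
        })
    }, integer(length(snpIdx)))
    fixedAllele <- matrix(fixedAllele, nrow = length(snpIdx))
    shared <- apply(fixedAllele, 1L, function(x)
        !anyNA(x) && length(unique(x)) == 1L)
    if (!any(shared)) return(NULL)
    runs <- rle(shared)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    cand <- which(runs$values)
    span <- start(rr)[snpIdx[ends[cand]]] - start(rr)[snpIdx[starts[cand]]]
    best <- cand[which.max(span)]      # widest bp span; first on ties
    idx <- snpIdx[starts[best]:ends[best]]
    ans <- GRanges(chr, IRanges(start(rr)[idx[1L]],
                                start(rr)[idx[length(idx)]]))
    ans$breeds <- paste(sort(ub), collapse = ",")
    ans$n_breeds <- length(ub)
    ans$n_snps <- length(idx)
    ans
}

#' Shared cores across all clusters
#'
#' Convenience wrapper: clusters the cores, then extracts the maximal
#' identity-by-state interval of every cluster spanning at least
#' `minBreeds` breeds.
#'
#' @param panel a [GenotypePanel-class]
#' @param cores `GRanges` from [homozygousCores]
#' @param minBreeds minimum breeds per reported cluster
#' @return `GRanges` of shared cores (possibly empty)
#' @export
sharedCores <- function(panel, cores, minBreeds = 2L) {
    cc <- clusterCores(cores)
    out <- list()
    for (cl in unique(cc$cluster)) {
        sub <- cc[cc$cluster == cl]
        if (length(unique(sub$breed)) < minBreeds) next
        ibs <- maximalIbs(sub, panel)
        if (!is.null(ibs)) { ibs$cluster <- cl; out[[length(out) + 1L]] <- ibs }
    }
    if (length(out) == 0L)
        return(GRanges(breeds = character(), n_breeds = integer(),
                       n_snps = integer(), cluster = integer()))
    unlist(GRangesList(out), use.names = FALSE)
}
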