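#' Multi-population Weir-Cockerham F_ST per locus
#'
#' The 1984 theta estimator computed per locus across the given breeds,
#' from per-breed allele frequency, sample size and observed heterozygote
#' fraction. Breeds with undefined frequency at a locus are dropped from
#' that locus; loci with fewer than two defined breeds, or monomorphic for
#' the same allele in every defined breed, return `NA`. Estimates are not
#' clipped here (negative values are retained for downstream moment
#' computations); [snpFstTable] clips for reporting.
#'
#' @param freqs a [BreedFreq-class]
#' @param breedSubset breeds to include (default: all columns)
#' @return numeric vector, one (possibly negative) theta per locus
#' @export
fstMulti <- function(freqs, breedSubset = NULL) {
    comps <- .wcComponents(freqs, breedSubset)
    theta <- comps$a / (comps$a + comps$b + comps$c)
    theta[!is.finite(theta)] <- NA_real_
    unname(theta)
}

# vectorized Weir & Cockerham (1984) a/b/c variance components per locus
.wcComponents <- function(freqs, breedSubset = NULL) {
    p <- freqs@freqB; n <- freqs@nInd; h <- freqs@hetObs
    if (!is.null(breedSubset)) {
        p <- p[, breedSubset, drop = FALSE]
        n <- n[, breedSubset, drop = FALSE]
        h <- h[, breedSubset, drop = FALSE]
    }
    def <- !is.na(p) & n > 0
    p0 <- ifelse(def, p, 0); n0 <- ifelse(def, n, 0)
    h0 <- ifelse(def, ifelse(is.na(h), 0, h), 0)
    r <- rowSums(def)
    sn <- rowSums(n0)
    nbar <- sn / r
    nc <- (sn - rowSums(n0^2) / sn) / (r - 1)
    pbar <- rowSums(n0 * p0) / sn
    s2 <- rowSums(n0 * (p0 - pbar)^2) / ((r - 1) * nbar)
    hbar <- rowSums(n0 * h0) / sn
    inner <- pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4
    a <- nbar / nc * (s2 - inner / (nbar - 1))
    b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    bad <- r < 2 | nbar <= 1
    a[bad] <- b[bad] <- cc[bad] <- NA_real_
    list(a = a, b = b, c = cc)
}

#' Pairwise F_ST between two breeds per locus
#'
#' Weir-Cockerham theta restricted to two breeds (the default), or the
#' Hudson/Bhatia ratio estimator behind the `estimator` flag for
#' sensitivity checks.
#'
#' @param freqs a [BreedFreq-class]
#' @param breedI,breedJ breed names
#' @param estimator `"wc"` or `"hudson"`
#' @return numeric vector of per-locus estimates (unclipped)
#' @export
fstPair <- function(freqs, breedI, breedJ, estimator = c("wc", "hudson")) {
    estimator <- match.arg(estimator)
    if (estimator == "wc")
        return(fstMulti(freqs, c(breedI, breedJ)))
    p1 <- freqs@freqB[, breedI]; p2 <- freqs@freqB[, breedJ]
    n1 <- freqs@nCalled[, breedI]; n2 <- freqs@nCalled[, breedJ]
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    theta <- num / den
    theta[!is.finite(theta)] <- NA_real_
    theta
}

#' Pairwise fixation index pq
#'
#' `p` counts breeds where allele A is fixed or close to fixation
#' (frequency > `fixThreshold`), `q` counts breeds near-fixed for allele B;
#' the index is the product `p * q`. A positive value means at least two
#' breeds are near-fixed for opposite alleles.
#'
#' @param freqs a [BreedFreq-class]
#' @param fixThreshold near-fixation frequency threshold
#' @return integer vector per locus
#' @export
pairwiseFixationIndex <- function(freqs, fixThreshold = 0.95) {
    f <- freqs@freqB
    p <- rowSums(f < 1 - fixThreshold, na.rm = TRUE)   # freq_A > threshold
    q <- rowSums(f > fixThreshold, na.rm = TRUE)
    as.integer(p * q)
}

#' Pooled minor allele frequency per locus
#'
#' Computed over all samples pooled (allele counts summed across breeds),
#' folded to `[0, 0.5]`.
#'
#' @param freqs a [BreedFreq-class]
#' @export
mafOverall <- function(freqs) {
    nb <- rowSums(freqs@freqB * freqs@nCalled, na.rm = TRUE)
    nc <- rowSums(freqs@nCalled, na.rm = TRUE)
    f <- nb / nc
    pmin(f, 1 - f)
}

#' Per-SNP differentiation table
#'
#' Combines the all-breed Weir-Cockerham F_ST (clipped to `[0, 1]` for
#' thresholding), pooled minor allele frequency and the pairwise fixation
#' index into one table for the high-F_ST screen.
#'
#' @param freqs a [BreedFreq-class]
#' @param breedSubset breeds entering F_ST (MAF stays panel-wide pooled)
#' @param fixThreshold see [pairwiseFixationIndex]
#' @return `GRanges` with mcols `fst`, `maf`, `pq`
#' @export
snpFstTable <- function(freqs, breedSubset = NULL, fixThreshold = 0.95) {
    gr <- freqs@loci
    theta <- fstMulti(freqs, breedSubset)
    mcols(gr)$fst <- pmin(pmax(theta, 0), 1)
    mcols(gr)$maf <- mafOverall(freqs)
    mcols(gr)$pq <- pairwiseFixationIndex(freqs, fixThreshold)
    gr
}

#' Cluster extreme-F_ST SNPs into regions
#'
#' SNPs passing both thresholds are chained whenever consecutive passing
#' SNPs on one chromosome are at most `mergeBp` apart; region bounds are
#' the first and last member SNP positions.
#'
#' @param table output of [snpFstTable]
#' @param fstMin,mafMin screen thresholds
#' @param mergeBp chaining distance in bp
#' @return `GRanges` of regions with mcols `n_snps`, `max_fst`
#' @export
highFstRegions <- function(table, fstMin = 0.55, mafMin = 0.15,
                           mergeBp = 500000L) {
    pass <- !is.na(table$fst) & table$fst > fstMin & table$maf > mafMin
    snps <- table[pass]
    if (length(snps) == 0L)
        return(GRanges(n_snps = integer(), max_fst = numeric()))
    regions <- reduce(granges(snps), min.gapwidth = mergeBp)
    ov <- findOverlaps(regions, snps)
    regions$n_snps <- tabulate(queryHits(ov), length(regions))
    regions$max_fst <- unname(vapply(
        split(snps$fst[subjectHits(ov)], queryHits(ov)), max, numeric(1)))
    sort(regions)
}
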