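#' Extended haplotype homozygosity over a SNP interval
#'
#' Probability that two distinct haplotypes drawn at random are identical
#' at every SNP in the closed index interval `[a, b]`:
#' `sum_k C(n_k, 2) / C(N, 2)` over distinct haplotype classes. Symmetric
#' in `a`, `b` and non-increasing as the interval widens.
#'
#' @param haps 0/1 haplotype matrix, loci x haplotypes
#' @param a,b row indices bounding the interval
#' @return a value in `[0, 1]`
#' @export
ehhBetween <- function(haps, a, b) {
    N <- ncol(haps)
    if (N < 2L) stop("need >= 2 haplotypes")
    sl <- haps[min(a, b):max(a, b), , drop = FALSE]
    key <- apply(sl, 2L, paste, collapse = "")
    nk <- table(key)
    sum(choose(nk, 2)) / choose(N, 2)
}

# incremental haplotype-class refinement: ids partition columns; returns
# updated ids after appending one more SNP row
.refineClasses <- function(ids, alleles) {
    comb <- ids * 2L + alleles
    match(comb, unique(comb))
}

.ehhFromIds <- function(ids, N) {
    nk <- tabulate(ids)
    sum(nk * (nk - 1)) / (N * (N - 1))
}

#' Select SNP pairs whose pooled EHH falls in a band
#'
#' Removes SNPs with pooled minor allele frequency below `mafMin`, then for
#' each remaining anchor scans outward in each direction for the nearest
#' partner SNP whose pooled (all-breed) EHH over the closed interval lies
#' in `[ehhLo, ehhHi]`. EHH is non-increasing outward, so the scan stops as
#' soon as it falls below `ehhLo`; anchors whose EHH jumps over the band in
#' a direction contribute no pair there.
#'
#' @param panel a phased [GenotypePanel-class]
#' @param ehhLo,ehhHi the retention band
#' @param mafMin pooled MAF filter
#' @return `DataFrame` with columns `anchor`, `partner` (locus indices into
#'   `panel`), `chrom`, `ehh`
#' @export
selectPairs <- function(panel, ehhLo = 0.03, ehhHi = 0.05, mafMin = 0.05) {
    stopifnot(isPhased(panel))
    H <- haplotypes(panel)
    N <- ncol(H)
    maf <- pmin(rowMeans(H), 1 - rowMeans(H))
    keep <- which(maf >= mafMin)
    chrom <- as.character(seqnames(rowRanges(panel)))
    res <- list()
    for (ai in seq_along(keep)) {
        a <- keep[ai]
        for (dir in c(1L, -1L)) {
            ids <- .refineClasses(rep(1L, N), H[a, ])
            bi <- ai
            repeat {
                bi <- bi + dir
                if (bi < 1L || bi > length(keep)) break
                b <- keep[bi]
                if (chrom[b] != chrom[a]) break
                ids <- .refineClasses(ids, H[b, ])
                e <- .ehhFromIds(ids, N)
                if (e < ehhLo) break
                if (e <= ehhHi) {
                    res[[length(res) + 1L]] <-
                        data.frame(anchor = a, partner = b,
                                   chrom = chrom[a], ehh = e)
                    break
                }
            }
        }
    }
    if (length(res) == 0L)
        return(DataFrame(anchor = integer(), partner = integer(),
                         chrom = character(), ehh = numeric()))
    DataFrame(do.call(rbind, res))
}

# per-breed integrated EHH (trapezoid over bp) from anchor to partner
.breedIhh <- function(H, cols, path, pos) {
    ids <- rep(1L, length(cols))
    ehh <- numeric(length(path))
    for (k in seq_along(path)) {
        ids <- .refineClasses(ids, H[path[k], cols])
        ehh[k] <- .ehhFromIds(ids, length(cols))
    }
    x <- abs(pos[path] - pos[path[1L]])
    if (length(path) < 2L) return(0)
    sum(diff(x) * (head(ehh, -1L) + tail(ehh, -1L)) / 2)
}

#' Breed-vs-rest XP-EHH scores for selected SNP pairs
#'
#' For every breed i and retained pair, integrates the breed's EHH from
#' anchor to partner over physical distance (iHH_i) and forms the raw log
#' ratio `ln(iHH_i / mean_{j != i} iHH_j)`, positive when breed i carries
#' unusually long shared haplotypes. Raw scores are z-standardized within
#' each breed x chromosome and the final score is the negated z-score, so
#' that swept breeds score negative in sweep regions (genome-wide mean 0,
#' sd 1 per breed and chromosome). Pairs with a zero numerator or
#' denominator for a breed are dropped for that breed with a count
#' reported.
#'
#' @param pairs output of [selectPairs]
#' @param panel the phased [GenotypePanel-class]
#' @return `DataFrame`: `breed`, `anchor`, `partner`, `chrom`, `raw`,
#'   `score`
#' @export
xpehhScores <- function(pairs, panel) {
    ub <- breedNames(panel)
    if (length(ub) < 2L) stop("need >= 2 breeds")
    H <- haplotypes(panel)
    hb <- haplotypeBreeds(panel)
    pos <- start(rowRanges(panel))
    n <- nrow(pairs)
    ihh <- matrix(NA_real_, n, length(ub), dimnames = list(NULL, ub))
    for (k in seq_len(n)) {
        path <- pairs$anchor[k]:pairs$partner[k]
        for (b in ub)
            ihh[k, b] <- .breedIhh(H, which(hb == b), path, pos)
    }
    out <- list()
    dropped <- 0L
    for (b in ub) {
        others <- rowMeans(ihh[, colnames(ihh) != b, drop = FALSE])
        ok <- ihh[, b] > 0 & others > 0
        dropped <- dropped + sum(!ok)
        raw <- log(ihh[ok, b] / others[ok])
        df <- data.frame(breed = b, anchor = pairs$anchor[ok],
                         partner = pairs$partner[ok],
                         chrom = pairs$chrom[ok], raw = raw)
        df$score <- NA_real_
        for (ch in unique(df$chrom)) {
            sel <- df$chrom == ch
            df$score[sel] <- -.zscore(df$raw[sel])
        }
        out[[b]] <- df
    }
    if (dropped > 0L)
        message("xpehhScores: dropped ", dropped,
                " breed-pair score(s) with zero iHH")
    DataFrame(do.call(rbind, out))
}

# z-standardization; idempotent on already-standardized input
.zscore <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x)) / s
}

#' Mean XP-EHH of candidate regions
#'
#' Mean normalized score over pairs whose anchor SNP lies inside the
#' region, for the region's breed. `NA` when a region contains no anchors
#' (reported as missing). The genome-wide mean per breed is 0 by
#' construction, so negative region means indicate fixation-length
#' haplotypes in the region's breed.
#'
#' @param scores output of [xpehhScores]
#' @param regions `GRanges` with a `breed` metadata column
#' @param panel the panel (for anchor positions)
#' @return numeric vector over regions (mean score)
#' @export
regionMeanXpehh <- function(scores, regions, panel) {
    pos <- start(rowRanges(panel))
    chrom <- as.character(seqnames(rowRanges(panel)))
    vapply(seq_along(regions), function(k) {
        b <- regions$breed[k]
        sel <- scores$breed == b &
            scores$chrom == as.character(seqnames(regions[k])) &
            pos[scores$anchor] >= start(regions[k]) &
            pos[scores$anchor] <= end(regions[k])
        if (!any(sel)) return(NA_real_)
        mean(scores$score[sel])
    }, numeric(1))
}
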