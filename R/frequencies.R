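#' Per-breed B-allele frequencies
#'
#' Tallies non-missing alleles per breed and locus. Diploid samples
#' contribute two alleles; at non-recombining X loci, male samples
#' contribute a single allele (their 0/2 dosage counts as one A or one B)
#' and never count as heterozygous. A breed with zero called alleles at a
#' locus gets `NA` frequency (the undefined flag) and is excluded from that
#' locus's cross-breed statistics downstream.
#'
#' @param panel a [GenotypePanel-class]
#' @return a [BreedFreq-class]
#' @export
breedFrequencies <- function(panel) {
    g <- genotypes(panel)
    br <- breeds(panel)
    ub <- unique(br)
    sex <- as.character(colData(panel)$sex)
    xnr <- chromClass(panel) == "X_nonrec"
    L <- nrow(g)
    called <- !is.na(g)
    # per-sample allele weight: 2, except males at X_nonrec loci contribute 1
    w <- matrix(2, L, ncol(g))
    if (any(xnr)) {
        male <- !is.na(sex) & sex == "M"
        w[xnr, male] <- 1
    }
    w[!called] <- 0
    bAll <- g / 2 * w          # B alleles contributed (0/2 male dosage -> 0/1)
    bAll[!called] <- 0
    het <- g == 1L & w == 2    # male X never heterozygous
    het[!called] <- FALSE
    freqB <- nCalled <- hetObs <- nInd <- matrix(
        NA_real_, L, length(ub), dimnames = list(NULL, ub))
    for (b in ub) {
        cols <- br == b
        nc <- rowSums(w[, cols, drop = FALSE])
        nb <- rowSums(bAll[, cols, drop = FALSE])
        ni <- rowSums(called[, cols, drop = FALSE])
        nh <- rowSums(het[, cols, drop = FALSE])
        nCalled[, b] <- nc
        nInd[, b] <- ni
        freqB[, b] <- ifelse(nc > 0, nb / nc, NA_real_)
        hetObs[, b] <- ifelse(ni > 0, nh / ni, NA_real_)
    }
    new("BreedFreq", freqB = freqB, nCalled = nCalled, hetObs = hetObs,
        nInd = nInd, loci = rowRanges(panel))
}

#' Assemble a BreedFreq from plain frequency tables
#'
#' Convenience constructor for hand-built tables (oracle tests, external
#' summaries). When observed heterozygosity is not given it defaults to the
#' Hardy-Weinberg expectation `2p(1-p)`.
#'
#' @param freqB loci x breeds matrix of B-allele frequencies
#' @param nCalled matching matrix of called-allele counts
#' @param hetObs optional matrix of observed heterozygote fractions
#' @param loci optional `GRanges`; defaults to consecutive positions on one
#'   autosome
#' @export
makeBreedFreq <- function(freqB, nCalled, hetObs = NULL, loci = NULL) {
    freqB <- as.matrix(freqB); nCalled <- as.matrix(nCalled)
    if (is.null(colnames(freqB)))
        colnames(freqB) <- paste0("V", seq_len(ncol(freqB)))
    dimnames(nCalled) <- dimnames(freqB)
    rownames(freqB) <- NULL
    if (is.null(hetObs)) hetObs <- 2 * freqB * (1 - freqB)
    if (is.null(loci))
        loci <- GRanges("chr1", IRanges(seq_len(nrow(freqB)), width = 1L),
                        alleleA = "A", alleleB = "B", chromClass = "autosome")
    new("BreedFreq", freqB = freqB, nCalled = nCalled,
        hetObs = as.matrix(hetObs), nInd = nCalled / 2, loci = loci)
}

#' @describeIn makeBreedFreq frequency matrix accessor
#' @param x a BreedFreq
#' @export
freqB <- function(x) x@freqB

#' @describeIn makeBreedFreq called-allele count accessor
#' @export
nCalled <- function(x) x@nCalled

#' @describeIn makeBreedFreq loci accessor
#' @export
freqLoci <- function(x) x@loci
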