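# shared fixture builders; everything generated in code

# panel from an explicit dosage matrix (loci x samples)
toyPanel <- function(geno, breed, pos = NULL, chrom = "chr1",
                     chromClass = "autosome", sex = NULL,
                     hapA = NULL, hapB = NULL) {
    geno <- as.matrix(geno)
    if (is.null(pos)) pos <- seq_len(nrow(geno)) * 1000L
    loci <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(pos, width = 1L),
        alleleA = "A", alleleB = "B", chromClass = chromClass)
    GenotypePanel(geno, loci, breed = breed, sex = sex,
                  hapA = hapA, hapB = hapB,
                  sampleIds = paste0("s", seq_len(ncol(geno))))
}

# phased panel from a haplotype matrix (loci x 2*samples, interleaved)
phasedPanel <- function(haps, breed, pos = NULL, chrom = "chr1") {
    haps <- as.matrix(haps)
    nS <- ncol(haps) / 2L
    a <- haps[, seq(1L, ncol(haps), 2L), drop = FALSE]
    b <- haps[, seq(2L, ncol(haps), 2L), drop = FALSE]
    toyPanel(a + b, breed = breed, pos = pos, chrom = chrom,
             hapA = a, hapB = b)
}

# random unphased panel: per-breed allele frequencies drawn uniformly
randomPanel <- function(nBreeds = 3L, nPer = 4L, L = 50L, seed = 1L,
                        missingProb = 0) {
    set.seed(seed)
    breed <- rep(paste0("B", seq_len(nBreeds)), each = nPer)
    g <- matrix(0L, L, nBreeds * nPer)
    for (b in seq_len(nBreeds)) {
        p <- runif(L)
        cols <- which(breed == paste0("B", b))
        for (s in cols) g[, s] <- rbinom(L, 2L, p)
    }
    if (missingProb > 0)
        g[matrix(runif(length(g)) < missingProb, nrow(g))] <- NA_integer_
    toyPanel(g, breed = breed, pos = sort(sample(1e6, L)))
}

# random phased panel built from per-breed haplotype pools (creates LD-free
# data; fine for combinatorial oracles)
randomPhasedPanel <- function(nBreeds = 2L, nPer = 4L, L = 30L, seed = 1L) {
    set.seed(seed)
    breed <- rep(paste0("B", seq_len(nBreeds)), each = nPer)
    haps <- matrix(rbinom(L * 2L * nBreeds * nPer, 1L, 0.5), L)
    phasedPanel(haps, breed = breed, pos = sort(sample(1e6, L)))
}

# scalar transcription of Weir & Cockerham (1984) theta for one locus --
# the independent oracle; p/nInd/het are per-population vectors
wcThetaOracle <- function(p, nInd, het = NULL) {
    if (is.null(het)) het <- 2 * p * (1 - p)
    r <- length(p)
    nbar <- mean(nInd)
    nc <- (r * nbar - sum(nInd^2) / (r * nbar)) / (r - 1)
    pbar <- sum(nInd * p) / (r * nbar)
    s2 <- sum(nInd * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(nInd * het) / (r * nbar)
    a <- nbar / nc *
        (s2 - 1 / (nbar - 1) *
             (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 -
             (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a / (a + b + cc)
}

# small fixed demographic scale used by simulation-backed tests
testModel <- function() demographicModel()

testBreeds <- function(n = 4L, size = 8L, f = 0.01)
    data.frame(name = paste0("B", seq_len(n)), n = size, f = f)
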