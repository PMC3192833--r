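#' Assign breed-level phenotypes to samples
#'
#' Every dog carries its breed's trait value; samples of breeds absent from
#' the trait table are dropped.
#'
#' @param panel a [GenotypePanel-class]
#' @param trait a [TraitTable-class]
#' @return list with `panel` (subset) and `phenotype` (aligned numeric)
#' @export
assignPhenotypes <- function(panel, trait) {
    vals <- traitValues(trait)
    keep <- breeds(panel) %in% names(vals)
    if (!any(keep))
        stop("no overlap between trait breeds and panel breeds")
    sub <- panel[, keep]
    list(panel = sub, phenotype = unname(vals[breeds(sub)]))
}

#' Single-SNP trend association
#'
#' Per-SNP simple linear regression of phenotype on B-allele dosage. The
#' statistic is the squared t of the slope; dichotomous 0/1 phenotypes go
#' through the same regression (equivalent to an allelic trend test up to a
#' monotone transform). Monomorphic loci get statistic 0 and p 1; loci with
#' fewer than 3 called samples are excluded (`NA`).
#'
#' @param geno dosage matrix, loci x samples
#' @param phenotype numeric vector over samples
#' @return list of vectors `stat` (t-squared) and `p`
#' @export
snpAssociation <- function(geno, phenotype) {
    if (var(phenotype) == 0) stop("phenotype has zero variance")
    stat <- .trendStat(geno, phenotype)
    n <- rowSums(!is.na(geno))
    p <- pf(stat, 1, n - 2, lower.tail = FALSE)
    p[!is.na(stat) & stat == 0] <- 1
    list(stat = stat, p = p)
}

# vectorized per-row regression t^2 of y on x; NA dosages excluded per row
.trendStat <- function(geno, y) {
    ok <- !is.na(geno)
    n <- rowSums(ok)
    g0 <- ifelse(ok, geno, 0)
    sy <- as.vector(ok %*% y); syy <- as.vector(ok %*% y^2)
    sx <- rowSums(g0); sxx <- rowSums(g0^2)
    sxy <- as.vector(g0 %*% y)
    cxx <- sxx - sx^2 / n
    cyy <- syy - sy^2 / n
    cxy <- sxy - sx * sy / n
    r2 <- ifelse(cxx > 0 & cyy > 0, cxy^2 / (cxx * cyy), 0)
    r2 <- pmin(r2, 1)
    stat <- (n - 2) * r2 / (1 - r2)
    stat[r2 >= 1] <- Inf
    stat[cxx == 0] <- 0            # monomorphic
    stat[n < 3] <- NA_real_
    stat
}

# tie-tolerant >= (max-T tallies must not depend on float round-off)
.geTol <- function(a, b) {
    if (!is.finite(b)) return(a >= b)
    a >= b - 1e-8 * pmax(1, abs(b))
}

# all orderings of 1..n (n small), one per row
.allOrderings <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- .allOrderings(n - 1L)
    out <- matrix(0L, n * nrow(sub), n)
    r <- 0L
    for (k in seq_len(n)) {
        rows <- r + seq_len(nrow(sub))
        out[rows, 1L] <- k
        out[rows, -1L] <- ifelse(sub >= k, sub + 1L, sub)
        r <- r + nrow(sub)
    }
    out
}

#' Across-breed GWAS with breed-label max-T permutation
#'
#' Runs the single-SNP trend test, then determines genome-wide significance
#' by permuting the breed phenotype values among breeds (every dog of a
#' breed always shares one value), recording the genome-wide maximum
#' statistic of each permutation:
#' `P_genome(snp) = (1 + #perms with max >= observed) / (1 + nPerm)`.
#' When the permutation space (`n_breeds!` orderings) does not exceed
#' `nPerm`, all orderings are enumerated instead and the plain proportion
#' over the `n!` orderings (identity included) is reported.
#'
#' @param panel a [GenotypePanel-class]
#' @param trait a [TraitTable-class]
#' @param nPerm number of permutations
#' @param seed RNG seed (reproducibility contract)
#' @param femalesOnly drop male samples first (X-chromosome protocol)
#' @return list: `stat`, `rawP`, `pGenome` per locus, `permMax`
#'   (per-permutation maxima), `exhaustive`, `nPerm`, `seed`, `loci`
#' @export
genomewidePermutation <- function(panel, trait, nPerm = 1000L, seed = 1L,
                                  femalesOnly = FALSE) {
    if (nPerm < 1L) stop("nPerm must be >= 1")
    if (femalesOnly) {
        sex <- as.character(colData(panel)$sex)
        panel <- panel[, !is.na(sex) & sex == "F"]
    }
    ap <- assignPhenotypes(panel, trait)
    panel <- ap$panel
    br <- breeds(panel)
    ub <- unique(br)
    if (length(ub) < 3L) stop("need >=3 breeds for breed permutation")
    vals <- traitValues(trait)[ub]
    g <- genotypes(panel)
    obs <- snpAssociation(g, ap$phenotype)
    space <- factorial(length(ub))
    exhaustive <- space <= nPerm
    if (exhaustive) {
        ords <- .allOrderings(length(ub))
        message("permutation space (", nrow(ords),
                ") <= nPerm; enumerating exhaustively")
        permMax <- apply(ords, 1L, function(o) {
            ph <- unname(vals[o][match(br, ub)])
            if (var(ph) == 0) return(-Inf)
            max(.trendStat(g, ph), na.rm = TRUE)
        })
        pGenome <- vapply(obs$stat, function(s)
            mean(.geTol(permMax, s)), numeric(1))
    } else {
        set.seed(seed)
        permMax <- vapply(seq_len(nPerm), function(k) {
            ph <- unname(vals[sample(length(ub))][match(br, ub)])
            if (var(ph) == 0) return(-Inf)
            max(.trendStat(g, ph), na.rm = TRUE)
        }, numeric(1))
        pGenome <- vapply(obs$stat, function(s)
            (1 + sum(.geTol(permMax, s))) / (1 + nPerm), numeric(1))
    }
    pGenome[is.na(obs$stat)] <- NA_real_
    list(stat = obs$stat, rawP = obs$p, pGenome = pGenome,
         permMax = permMax, exhaustive = exhaustive, nPerm = nPerm,
         seed = seed, loci = rowRanges(panel))
}
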