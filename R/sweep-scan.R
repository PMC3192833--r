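# chromosome-class pooling used for standardization: autosomes + PAR
# together, non-recombining X on its own
.scanClass <- function(cls) ifelse(cls == "X_nonrec", "X_nonrec", "auto")

# windows x breeds matrix of polymorphic-SNP counts
.windowPolyCounts <- function(freqs, windows) {
    poly <- !is.na(freqs@freqB) & freqs@freqB > 0 & freqs@freqB < 1
    M <- .windowMembership(windows, freqs@loci)
    as.matrix(M %*% poly)
}

#' Relative heterozygosity of a breed pair in windows
#'
#' theta_ij = h_i / (h_i + h_j) where h is the count of SNPs polymorphic in
#' that breed within the window. `NA` when neither breed segregates in a
#' window (the pair is skipped there). theta_ij + theta_ji = 1 wherever
#' defined.
#'
#' @param freqs a [BreedFreq-class]
#' @param windows `GRanges` from [makeWindows]
#' @param breedI,breedJ breed names
#' @return numeric vector over windows
#' @export
relativeHeterozygosity <- function(freqs, windows, breedI, breedJ) {
    H <- .windowPolyCounts(freqs, windows)
    tot <- H[, breedI] + H[, breedJ]
    unname(ifelse(tot > 0, H[, breedI] / tot, NA_real_))
}

#' Windowed S_i scan
#'
#' For every breed i and retained window, sums the standardized relative
#' heterozygosity over all breed pairs:
#' `S_i = sum_j (theta_ij - E[theta_ij]) / sd[theta_ij]`. The expectation is
#' the pooled genome-wide ratio `H_i / (H_i + H_j)` of polymorphic-SNP
#' counts; the standard deviation is taken over all window theta values of
#' the pair. Moments are computed separately for autosome+PAR windows and
#' non-recombining X windows. Pairs with undefined theta in a window are
#' skipped there without rescaling the sum; pairs whose window sd is zero
#' are excluded with a warning. Strongly negative S_i flags loss of
#' variation in breed i.
#'
#' @param freqs a [BreedFreq-class]
#' @param windows `GRanges` from [makeWindows]
#' @param breedSubset breeds to scan (default all)
#' @return a [WindowStatTrack-class] with statistic `"si"`
#' @export
siScan <- function(freqs, windows, breedSubset = NULL) {
    bn <- colnames(freqs@freqB)
    if (!is.null(breedSubset)) bn <- intersect(bn, breedSubset)
    if (length(bn) < 2L) stop("need >=2 breeds")
    H <- .windowPolyCounts(freqs, windows)[, bn, drop = FALSE]
    poly <- (!is.na(freqs@freqB) & freqs@freqB > 0 &
             freqs@freqB < 1)[, bn, drop = FALSE]
    wcls <- .scanClass(windows$chromClass)
    lcls <- .scanClass(as.character(mcols(freqs@loci)$chromClass))
    S <- matrix(0, length(windows), length(bn), dimnames = list(NULL, bn))
    nP <- matrix(0L, length(windows), length(bn), dimnames = list(NULL, bn))
    mom <- list()
    for (cl in unique(wcls)) {
        wIdx <- which(wcls == cl)
        G <- colSums(poly[lcls == cl, , drop = FALSE])
        for (i in seq_along(bn)) for (j in seq_along(bn)) {
            if (i >= j) next
            hi <- H[wIdx, i]; hj <- H[wIdx, j]
            tot <- hi + hj
            th <- ifelse(tot > 0, hi / tot, NA_real_)
            sdv <- sd(th, na.rm = TRUE)
            eij <- G[i] / (G[i] + G[j])
            mom[[length(mom) + 1L]] <- DataFrame(
                breed_i = bn[i], breed_j = bn[j], chromClass = cl,
                expectation = eij, sd = sdv)
            if (!is.finite(sdv) || sdv == 0) {
                warning("pair ", bn[i], "/", bn[j], " (", cl,
                        ") excluded: zero sd of window theta")
                next
            }
            zi <- (th - eij) / sdv            # for breed i
            zj <- ((1 - th) - (1 - eij)) / sdv  # theta_ji, same sd
            def <- !is.na(th)
            S[wIdx[def], i] <- S[wIdx[def], i] + zi[def]
            S[wIdx[def], j] <- S[wIdx[def], j] + zj[def]
            nP[wIdx[def], i] <- nP[wIdx[def], i] + 1L
            nP[wIdx[def], j] <- nP[wIdx[def], j] + 1L
        }
    }
    S[nP == 0L] <- NA_real_
    new("WindowStatTrack", windows = windows, values = S, statistic = "si",
        moments = do.call(rbind, mom), nPairs = nP)
}

#' Per-SNP d_i and its windowed scan
#'
#' `d_i = sum_j (F_ST^ij - E[F_ST^ij]) / sd[F_ST^ij]` per SNP, with moments
#' taken over all SNPs of the chromosome class; the window value is the
#' mean of member-SNP d_i. Unclipped Weir-Cockerham pairwise estimates are
#' used so the moments are unbiased. Large positive d_i flags breed-specific
#' allele-frequency divergence.
#'
#' @inheritParams siScan
#' @param returnSnp also attach the per-SNP d_i matrix as attribute `snpDi`
#' @return a [WindowStatTrack-class] with statistic `"di"`
#' @export
diScan <- function(freqs, windows, breedSubset = NULL, returnSnp = FALSE) {
    bn <- colnames(freqs@freqB)
    if (!is.null(breedSubset)) bn <- intersect(bn, breedSubset)
    if (length(bn) < 2L) stop("need >=2 breeds")
    L <- nrow(freqs@freqB)
    lcls <- .scanClass(as.character(mcols(freqs@loci)$chromClass))
    dSnp <- matrix(0, L, length(bn), dimnames = list(NULL, bn))
    nDef <- matrix(0L, L, length(bn))
    mom <- list()
    for (i in seq_along(bn)) for (j in seq_along(bn)) {
        if (i >= j) next
        fst <- fstPair(freqs, bn[i], bn[j])
        for (cl in unique(lcls)) {
            sel <- lcls == cl
            e <- mean(fst[sel], na.rm = TRUE)
            sdv <- sd(fst[sel], na.rm = TRUE)
            mom[[length(mom) + 1L]] <- DataFrame(
                breed_i = bn[i], breed_j = bn[j], chromClass = cl,
                expectation = e, sd = sdv)
            if (!is.finite(sdv) || sdv == 0) {
                warning("pair ", bn[i], "/", bn[j], " (", cl,
                        ") excluded: zero sd of pairwise F_ST")
                next
            }
            z <- (fst[sel] - e) / sdv
            def <- !is.na(z)
            zz <- ifelse(def, z, 0)
            dSnp[sel, i] <- dSnp[sel, i] + zz
            dSnp[sel, j] <- dSnp[sel, j] + zz
            nDef[sel, i] <- nDef[sel, i] + def
            nDef[sel, j] <- nDef[sel, j] + def
        }
    }
    dSnp[nDef == 0L] <- NA_real_
    M <- .windowMembership(windows, freqs@loci)
    defm <- !is.na(dSnp)
    d0 <- ifelse(defm, dSnp, 0)
    num <- as.matrix(M %*% d0)
    den <- as.matrix(M %*% defm)
    vals <- ifelse(den > 0, num / den, NA_real_)
    colnames(vals) <- bn
    tr <- new("WindowStatTrack", windows = windows, values = vals,
              statistic = "di", moments = do.call(rbind, mom),
              nPairs = as.matrix(M %*% (nDef > 0L)))
    if (returnSnp) attr(tr, "snpDi") <- dSnp
    tr
}

#' @describeIn siScan statistic values (windows x breeds)
#' @param track a WindowStatTrack
#' @export
statValues <- function(track) track@values

#' @describeIn siScan window ranges of a track
#' @export
trackWindows <- function(track) track@windows

#' @describeIn siScan pair moments used for standardization
#' @export
pairMoments <- function(track) track@moments

#' Flag extreme-tail windows
#'
#' Flags, per breed, the `ceiling(tailFrac * N)` most extreme retained
#' windows: the low tail for S_i, the high tail for d_i. All windows tied
#' with the threshold value are included.
#'
#' @param track a [WindowStatTrack-class]
#' @param tailFrac tail fraction (default 0.01)
#' @return logical windows x breeds matrix
#' @export
tailWindows <- function(track, tailFrac = 0.01) {
    v <- track@values
    low <- track@statistic == "si"
    flags <- matrix(FALSE, nrow(v), ncol(v), dimnames = dimnames(v))
    for (b in seq_len(ncol(v))) {
        x <- v[, b]
        ok <- which(!is.na(x))
        if (length(ok) < 1 / tailFrac)
            stop("only ", length(ok), " windows with defined ",
                 track@statistic, " for breed ", colnames(v)[b],
                 "; need >= ", ceiling(1 / tailFrac))
        k <- ceiling(tailFrac * length(ok))
        s <- sort(x[ok], decreasing = !low)
        thr <- s[k]
        flags[, b] <- if (low) !is.na(x) & x <= thr else !is.na(x) & x >= thr
        if (all(flags[ok, b]))
            warning("all windows tied at the tail threshold for breed ",
                    colnames(v)[b])
    }
    flags
}

#' Collapse flagged windows into candidate regions
#'
#' Overlapping or exactly abutting flagged windows of one breed are merged
#' into maximal regions.
#'
#' @param track a [WindowStatTrack-class]
#' @param flags logical matrix from [tailWindows]
#' @return `GRanges` with mcols `breed`, `statistic`, `n_windows`,
#'   `length_bp`
#' @export
mergeToRegions <- function(track, flags) {
    out <- list()
    for (b in colnames(flags)) {
        w <- track@windows[flags[, b]]
        if (length(w) == 0L) next
        r <- reduce(granges(w))
        ov <- findOverlaps(r, w)
        r$breed <- b
        r$statistic <- track@statistic
        r$n_windows <- tabulate(queryHits(ov), length(r))
        r$length_bp <- width(r)
        out[[b]] <- r
    }
    if (length(out) == 0L)
        return(GRanges(breed = character(), statistic = character(),
                       n_windows = integer(), length_bp = integer()))
    unlist(GRangesList(out), use.names = FALSE)
}

#' Construct a null length distribution object
#'
#' @param lengths named list `statistic -> named list breed -> numeric`
#' @param descriptor free-form provenance list (model, seed)
#' @export
NullLengthDistribution <- function(lengths, descriptor = list()) {
    new("NullLengthDistribution", lengths = lengths, descriptor = descriptor)
}

#' @describeIn NullLengthDistribution null lengths for one breed/statistic
#' @param x a NullLengthDistribution
#' @param statistic "si" or "di"
#' @param breed breed name
#' @export
nullLengths <- function(x, statistic, breed) x@lengths[[statistic]][[breed]]

#' Assign marginal p and FDR q to candidate regions
#'
#' The marginal p-value of a region is the proportion of same-breed
#' same-statistic null regions that are strictly longer, with an add-one
#' numerator and denominator by default (`(1 + #longer) / (1 + n_null)`),
#' so that BH never receives an exact zero. `addOne = FALSE` gives the
#' plain proportion. q-values are Benjamini-Hochberg adjusted across all
#' regions of one statistic; `significant` marks `q <= alpha`.
#'
#' @param regions `GRanges` from [mergeToRegions]
#' @param null a [NullLengthDistribution-class]
#' @param alpha FDR level
#' @param addOne use the add-one p-value convention
#' @return `regions` with mcols `marginal_p`, `fdr_q`, `significant` added
#' @export
regionSignificance <- function(regions, null, alpha = 0.05, addOne = TRUE) {
    if (length(regions) == 0L) {
        regions$marginal_p <- numeric(); regions$fdr_q <- numeric()
        regions$significant <- logical()
        return(regions)
    }
    p <- vapply(seq_along(regions), function(k) {
        nl <- nullLengths(null, regions$statistic[k], regions$breed[k])
        if (is.null(nl) || length(nl) == 0L)
            stop("no null lengths for breed ", regions$breed[k],
                 " statistic ", regions$statistic[k])
        longer <- sum(nl > regions$length_bp[k])
        if (addOne) (1 + longer) / (1 + length(nl)) else longer / length(nl)
    }, numeric(1))
    regions$marginal_p <- p
    regions$fdr_q <- NA_real_
    for (st in unique(regions$statistic)) {
        sel <- regions$statistic == st
        regions$fdr_q[sel] <- p.adjust(p[sel], method = "BH")
    }
    regions$significant <- regions$fdr_q <= alpha
    regions
}
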