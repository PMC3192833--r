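# windowed S_i / d_i scans, tails, regions, length-null significance

# independent window-loop transcription of the S_i definition
siOracle <- function(fr, win, breeds) {
    poly <- !is.na(freqB(fr)) & freqB(fr) > 0 & freqB(fr) < 1
    idx <- windowSnpIndices(win, freqLoci(fr))
    H <- t(vapply(seq_along(win), function(w)
        colSums(poly[idx[[w]], breeds, drop = FALSE]), numeric(length(breeds))))
    G <- colSums(poly[, breeds, drop = FALSE])
    S <- matrix(0, length(win), length(breeds),
                dimnames = list(NULL, breeds))
    for (i in seq_along(breeds)) for (j in seq_along(breeds)) {
        if (i == j) next
        th <- ifelse(H[, i] + H[, j] > 0, H[, i] / (H[, i] + H[, j]), NA)
        e <- G[i] / (G[i] + G[j])
        s <- sd(th, na.rm = TRUE)
        z <- (th - e) / s
        S[, i] <- S[, i] + ifelse(is.na(z), 0, z)
    }
    S
}

test_that("relative heterozygosity follows the h_i/(h_i+h_j) definition", {
    # windows with hand-set polymorphic counts via an explicit freq table
    f <- cbind(B1 = c(rep(0.5, 10), rep(0, 30)),
               B2 = c(rep(0.5, 40))) # window1: h1=10, h2=40 over all loci
    loci <- GenomicRanges::GRanges("c1",
        IRanges::IRanges(seq(1000L, by = 1000L, length.out = 40), width = 1L),
        alleleA = "A", alleleB = "B", chromClass = "autosome")
    fr <- makeBreedFreq(f, nCalled = matrix(20, 40, 2), loci = loci)
    win <- makeWindows(loci, windowBp = 40000L, stepBp = 40000L, minSnps = 1L)
    expect_equal(relativeHeterozygosity(fr, win, "B1", "B2"), 10 / 50)
    expect_equal(relativeHeterozygosity(fr, win, "B2", "B1"), 40 / 50)
    # h_i = h_j > 0 -> 0.5
    fr2 <- makeBreedFreq(cbind(B1 = rep(0.5, 40), B2 = rep(0.5, 40)),
                         nCalled = matrix(20, 40, 2), loci = loci)
    expect_equal(relativeHeterozygosity(fr2, win, "B1", "B2"), 0.5)
    # h_i = 0 -> 0 and complement 1
    fr3 <- makeBreedFreq(cbind(B1 = rep(1, 40), B2 = rep(0.5, 40)),
                         nCalled = matrix(20, 40, 2), loci = loci)
    expect_equal(relativeHeterozygosity(fr3, win, "B1", "B2"), 0)
    expect_equal(relativeHeterozygosity(fr3, win, "B2", "B1"), 1)
    # both zero -> undefined
    fr4 <- makeBreedFreq(cbind(B1 = rep(1, 40), B2 = rep(0, 40)),
                         nCalled = matrix(20, 40, 2), loci = loci)
    expect_true(is.na(relativeHeterozygosity(fr4, win, "B1", "B2")))
})

test_that("theta complement holds and S_i matches the loop oracle", {
    pan <- randomPanel(nBreeds = 3L, nPer = 6L, L = 400L, seed = 21)
    fr <- breedFrequencies(pan)
    win <- makeWindows(pan, windowBp = 50000L, stepBp = 10000L, minSnps = 2L)
    # complement property
    tij <- relativeHeterozygosity(fr, win, "B1", "B2")
    tji <- relativeHeterozygosity(fr, win, "B2", "B1")
    ok <- !is.na(tij)
    expect_equal(tij[ok] + tji[ok], rep(1, sum(ok)))

    tr <- siScan(fr, win)
    expect_equal(statValues(tr), siOracle(fr, win, c("B1", "B2", "B3")))

    # centering: windows where theta == E for all pairs give S_i = 0 exactly
    # (constructed case: identical breeds)
    g <- genotypes(pan)
    panSame <- toyPanel(cbind(g[, 1:6], g[, 1:6]),
                        breed = rep(c("X", "Y"), each = 6L),
                        pos = start(rowRanges(pan)))
    frSame <- breedFrequencies(panSame)
    # identical breeds: non-degenerate pairs only, zero-sd pair is excluded
    trSame <- suppressWarnings(siScan(frSame, win))
    v <- statValues(trSame)
    expect_equal(v[, "X"], -v[, "Y"])   # two-breed antisymmetry
})

test_that("a fully homozygous window is the breed's S_i minimum", {
    set.seed(99)
    pan <- randomPanel(nBreeds = 3L, nPer = 8L, L = 500L, seed = 99)
    g <- genotypes(pan)
    pos <- start(rowRanges(pan))
    # wipe variation in B1 over a contiguous 150kb block
    block <- pos >= 4e5 & pos <= 5.5e5
    g[block, breeds(pan) == "B1"] <- 0L
    pan2 <- toyPanel(g, breed = breeds(pan), pos = pos)
    fr <- breedFrequencies(pan2)
    win <- makeWindows(pan2, windowBp = 150000L, stepBp = 25000L,
                       minSnps = 5L)
    tr <- siScan(fr, win)
    v <- statValues(tr)[, "B1"]
    wmin <- which.min(v)
    expect_true(start(trackWindows(tr))[wmin] <= 5.5e5 &&
                end(trackWindows(tr))[wmin] >= 4e5)
})

test_that("per-SNP d_i matches the hand-computed standardized sum", {
    pan <- randomPanel(nBreeds = 3L, nPer = 6L, L = 300L, seed = 33)
    fr <- breedFrequencies(pan)
    win <- makeWindows(pan, windowBp = 100000L, stepBp = 50000L,
                       minSnps = 1L)
    tr <- diScan(fr, win, returnSnp = TRUE)
    dSnp <- attr(tr, "snpDi")
    bn <- c("B1", "B2", "B3")
    # oracle: per-pair fst via scalar WC oracle, moments over SNPs
    fstm <- list()
    for (i in 1:2) for (j in (i + 1):3) {
        v <- vapply(seq_len(nrow(freqB(fr))), function(l)
            wcThetaOracle(freqB(fr)[l, c(i, j)], fr@nInd[l, c(i, j)],
                          fr@hetObs[l, c(i, j)]), numeric(1))
        fstm[[paste(i, j)]] <- v
    }
    dOr <- matrix(0, nrow(freqB(fr)), 3L)
    for (i in 1:2) for (j in (i + 1):3) {
        v <- fstm[[paste(i, j)]]
        z <- (v - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE)
        z0 <- ifelse(is.na(z), 0, z)
        dOr[, i] <- dOr[, i] + z0
        dOr[, j] <- dOr[, j] + z0
    }
    expect_equal(unname(dSnp), dOr)
    # window value is the mean of member-SNP d_i
    idx <- windowSnpIndices(win, pan)
    for (w in sample(length(win), 5L))
        expect_equal(unname(statValues(tr)[w, ]),
                     unname(colMeans(dSnp[idx[[w]], , drop = FALSE])))
    # standardization identity: mean 0, var 1 per pair over defined SNPs
    for (k in names(fstm)) {
        v <- fstm[[k]]
        z <- (v - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE)
        expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-12)
        expect_equal(sd(z, na.rm = TRUE), 1, tolerance = 1e-12)
    }
})

test_that("tail flagging equals sort-and-slice with tie inclusion", {
    pan <- randomPanel(nBreeds = 2L, nPer = 5L, L = 2000L, seed = 13)
    fr <- breedFrequencies(pan)
    win <- makeWindows(pan, windowBp = 5000L, stepBp = 2500L, minSnps = 1L)
    tr <- siScan(fr, win)
    fl <- tailWindows(tr, tailFrac = 0.01)
    for (b in colnames(fl)) {
        x <- statValues(tr)[, b]
        k <- ceiling(0.01 * sum(!is.na(x)))
        thr <- sort(x)[k]
        expect_identical(unname(fl[, b]), !is.na(x) & x <= thr)
        expect_gte(sum(fl[, b]), k)
    }
    # d_i flags the high tail
    trd <- diScan(fr, win)
    fld <- suppressWarnings(tailWindows(trd, tailFrac = 0.01))
    for (b in colnames(fld)) {
        x <- statValues(trd)[, b]
        k <- ceiling(0.01 * sum(!is.na(x)))
        thr <- sort(x, decreasing = TRUE)[k]
        expect_identical(unname(fld[, b]), !is.na(x) & x >= thr)
    }
    # degenerate ties: all values equal -> everything flagged, one warning
    # per breed
    trConst <- tr
    trConst@values[] <- 1
    w <- capture_warnings(flc <- tailWindows(trConst, 0.01))
    expect_length(w, ncol(flc))
    expect_true(all(grepl("tied", w)))
    expect_true(all(flc))
    # too few windows is fatal
    expect_error(tailWindows(tr, tailFrac = 1e-6), "need >=")
})

test_that("flagged windows merge into regions by interval union", {
    win <- GenomicRanges::GRanges("c1",
        IRanges::IRanges(c(1L, 25001L, 1000001L), width = 150000L))
    win$n_snps <- 10L; win$chromClass <- "autosome"
    tr <- new("WindowStatTrack", windows = win,
              values = matrix(0, 3, 1, dimnames = list(NULL, "B1")),
              statistic = "si", moments = S4Vectors::DataFrame(),
              nPairs = matrix(1L, 3, 1))
    fl <- matrix(TRUE, 3, 1, dimnames = list(NULL, "B1"))
    reg <- mergeToRegions(tr, fl)
    expect_length(reg, 2L)
    expect_equal(width(reg)[1L], 175000L)   # 0-175kb union
    expect_equal(reg$n_windows, c(2L, 1L))
    expect_equal(width(reg)[2L], 150000L)   # single window region
    # distant windows stay separate
    fl2 <- matrix(c(TRUE, FALSE, TRUE), 3, 1, dimnames = list(NULL, "B1"))
    expect_length(mergeToRegions(tr, fl2), 2L)
})

test_that("marginal p and BH follow the stated counting rules", {
    reg <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, width = 500000L))
    reg$breed <- "B1"; reg$statistic <- "si"; reg$n_windows <- 3L
    reg$length_bp <- 500000L
    null <- NullLengthDistribution(list(
        si = list(B1 = c(100000, 200000, 600000, 800000))))
    out <- regionSignificance(reg, null)
    expect_equal(out$marginal_p, (1 + 2) / (1 + 4))
    # plain proportion behind the flag
    out2 <- regionSignificance(reg, null, addOne = FALSE)
    expect_equal(out2$marginal_p, 2 / 4)
    # longer than every null region with n=999 -> 1/1000
    null2 <- NullLengthDistribution(list(si = list(B1 = rep(1e5, 999))))
    out3 <- regionSignificance(reg, null2)
    expect_equal(out3$marginal_p, 1 / 1000)
    # ties count as not longer (strict comparison)
    null3 <- NullLengthDistribution(list(si = list(B1 = rep(500000, 9))))
    out4 <- regionSignificance(reg, null3)
    expect_equal(out4$marginal_p, 1 / 10)
    # missing breed in the null is fatal
    regB <- reg; regB$breed <- "B9"
    expect_error(regionSignificance(regB, null), "no null lengths")
})

test_that("BH step-up matches a hand computation", {
    p <- c(0.001, 0.02, 0.03, 0.04)
    reg <- GenomicRanges::GRanges("c1",
        IRanges::IRanges(seq(1, by = 2e6, length.out = 4), width = 1e5))
    reg$breed <- paste0("B", 1:4); reg$statistic <- "si"
    reg$n_windows <- 1L; reg$length_bp <- rep(1e5, 4)
    # craft nulls of size 999 so the add-one marginal p equals the p-list
    nulls <- lapply(p, function(pp) {
        L <- pp * 1000 - 1
        c(rep(2e5, L), rep(5e4, 999 - L))
    })
    null <- NullLengthDistribution(list(si = setNames(nulls, paste0("B", 1:4))))
    out <- regionSignificance(reg, null, alpha = 0.05)
    expect_equal(out$marginal_p, p)
    # hand BH: all four rejected at alpha=0.05
    expect_true(all(out$significant))
    expect_equal(out$fdr_q, p.adjust(p, "BH"))
})

test_that("scan output is deterministic for identical input", {
    pan <- randomPanel(nBreeds = 3L, nPer = 4L, L = 300L, seed = 8)
    fr <- breedFrequencies(pan)
    win <- makeWindows(pan, windowBp = 50000L, stepBp = 25000L, minSnps = 2L)
    t1 <- siScan(fr, win); t2 <- siScan(fr, win)
    expect_identical(statValues(t1), statValues(t2))
    f1 <- tailWindows(t1, 0.05)
    r1 <- mergeToRegions(t1, f1)
    r2 <- mergeToRegions(t2, tailWindows(t2, 0.05))
    expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("E[theta] complement identity holds in pair moments", {
    pan <- randomPanel(nBreeds = 4L, nPer = 5L, L = 500L, seed = 55)
    fr <- breedFrequencies(pan)
    win <- makeWindows(pan, windowBp = 50000L, stepBp = 25000L, minSnps = 2L)
    tr <- siScan(fr, win)
    mom <- as.data.frame(pairMoments(tr))
    poly <- !is.na(freqB(fr)) & freqB(fr) > 0 & freqB(fr) < 1
    G <- colSums(poly)
    for (k in seq_len(nrow(mom))) {
        gi <- G[mom$breed_i[k]]; gj <- G[mom$breed_j[k]]
        expect_equal(mom$expectation[k], unname(gi / (gi + gj)))
    }
})
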