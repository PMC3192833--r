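# synthetic panel generation, ascertainment matching, LD decay, planting

test_that("same seed gives identical panels; bookkeeping is correct", {
    model <- testModel()
    bt <- data.frame(name = c("X", "Y", "Z", "W", "V"), n = 10L, f = 0.01)
    segs <- data.frame(lengthBp = 1e6, chromClass = "autosome")
    p1 <- simulateNeutralPanel(model, bt, segs, seed = 11L)
    p2 <- simulateNeutralPanel(model, bt, segs, seed = 11L)
    expect_identical(genotypes(p1), genotypes(p2))
    expect_identical(start(rowRanges(p1)), start(rowRanges(p2)))
    # 5 breeds x 10 samples -> 50 samples, 100 haplotypes
    expect_equal(ncol(p1), 50L)
    expect_equal(ncol(haplotypes(p1)), 100L)
    expect_true(isPhased(p1))
    expect_false(anyNA(genotypes(p1)))
    # a different seed changes the panel
    p3 <- simulateNeutralPanel(model, bt, segs, seed = 12L)
    expect_false(identical(start(rowRanges(p1)), start(rowRanges(p3))))
})

test_that("stronger bottlenecks reduce within-breed heterozygosity", {
    model <- testModel()
    segs <- data.frame(lengthBp = 1e6, chromClass = "autosome")
    # nucleotide diversity per bp within the breed
    het <- vapply(c(0.002, 0.01, 0.03), function(f) {
        hets <- vapply(1:4, function(k) {
            pan <- simulateNeutralPanel(
                model, data.frame(name = "B", n = 10L, f = f), segs,
                seed = 1000L + k)
            p <- rowMeans(haplotypes(pan))
            sum(2 * p * (1 - p)) / 1e6
        }, numeric(1))
        mean(hets)
    }, numeric(1))
    expect_true(het[1] < het[2] && het[2] < het[3])
})

test_that("ascertainment matching respects the target and the density", {
    model <- testModel()
    bt <- testBreeds(4L, 8L)
    pan <- simulateNeutralPanel(model, bt,
                                data.frame(lengthBp = 5e6,
                                           chromClass = "autosome"),
                                seed = 21L)
    thin <- ascertainmentMatch(pan, seed = 21L)
    # mean spacing within 10% of 13,046 bp
    spacing <- 5e6 / nrow(thin)
    expect_lt(abs(spacing - 13046) / 13046, 0.10)
    # order and phasing preserved
    expect_true(isPhased(thin))
    expect_false(is.unsorted(start(rowRanges(thin))))
    # retained histogram close to the uniform target (chi-square distance)
    g <- genotypes(thin)
    maf <- pmin(rowMeans(g) / 2, 1 - rowMeans(g) / 2)
    obs <- table(cut(maf, seq(0, 0.5, length.out = 11)))
    expF <- rep(nrow(thin) / 10, 10)
    chisq <- sum((as.vector(obs) - expF)^2 / expF) / nrow(thin)
    expect_lt(chisq, 0.5)
    # target mass only above MAF 0.3 -> nothing retained below
    thin2 <- ascertainmentMatch(pan, targetHist = c(0, 0, 0, 0, 0, 0,
                                                    1, 1, 1, 1),
                                seed = 5L)
    g2 <- genotypes(thin2)
    maf2 <- pmin(rowMeans(g2) / 2, 1 - rowMeans(g2) / 2)
    expect_true(all(maf2 > 0.3))
})

test_that("LD decay r2 matches a hand computation on a toy table", {
    # 8 haplotypes over 2 loci in known phase
    haps <- rbind(c(1, 1, 1, 0, 0, 0, 1, 0),
                  c(1, 1, 0, 0, 0, 1, 1, 0))
    pan <- phasedPanel(haps, breed = rep("A", 4L), pos = c(1000L, 6000L))
    cur <- ldDecay(pan, maxBp = 10000L, binBp = 10000L)
    pA <- mean(haps[1L, ]); pB <- mean(haps[2L, ])
    pAB <- mean(haps[1L, ] * haps[2L, ])
    r2 <- (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
    expect_equal(cur$mean_r2[1L], r2)
    expect_equal(cur$n_pairs[1L], 1)
    # perfect coupling -> 1
    haps2 <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0))
    pan2 <- phasedPanel(haps2, breed = rep("A", 2L), pos = c(1000L, 3000L))
    expect_equal(ldDecay(pan2, 10000L, 10000L)$mean_r2[1L], 1)
    # independent loci at large n stay near the 1/n sampling floor
    set.seed(13)
    n <- 400L
    haps3 <- rbind(rbinom(n, 1L, 0.5), rbinom(n, 1L, 0.5))
    pan3 <- phasedPanel(haps3, breed = rep("A", n / 2L),
                        pos = c(1000L, 3000L))
    expect_lt(ldDecay(pan3, 10000L, 10000L)$mean_r2[1L], 10 / n)
})

test_that("bottlenecked breeds show slower LD decay than the ancestral pool", {
    model <- testModel()
    segs <- data.frame(lengthBp = 2e6, chromClass = "autosome")
    panB <- simulateNeutralPanel(model,
                                 data.frame(name = "B", n = 10L, f = 0.005),
                                 segs, seed = 31L)
    # no-bottleneck control: breed kept at the ancestral dog size
    panC <- simulateNeutralPanel(model,
                                 data.frame(name = "B", n = 10L, f = 0.25),
                                 segs, seed = 31L)
    ldB <- ldDecay(panB, maxBp = 2e5, binBp = 5e4)
    ldC <- ldDecay(panC, maxBp = 2e5, binBp = 5e4)
    expect_true(mean(ldB$mean_r2, na.rm = TRUE) >
                mean(ldC$mean_r2, na.rm = TRUE))
})

test_that("planted sweeps fix the breed and leave everything else alone", {
    model <- testModel()
    bt <- testBreeds(3L, 6L)
    pan <- simulateNeutralPanel(model, bt,
                                data.frame(lengthBp = 3e6,
                                           chromClass = "autosome"),
                                seed = 41L)
    swept <- plantSweep(pan, "B1", "sim1", 1e6, 2e6, seed = 7L)
    rr <- rowRanges(pan)
    inside <- start(rr) >= 1e6 & start(rr) <= 2e6
    # breed B1 has zero polymorphism inside
    fr <- breedFrequencies(swept)
    expect_true(all(freqB(fr)[inside, "B1"] %in% c(0, 1)))
    # theta_B1,j = 0 in windows inside the region wherever defined
    win <- makeWindows(swept, 150000L, 150000L, 3L)
    th <- relativeHeterozygosity(fr, win, "B1", "B2")
    winInside <- start(win) >= 1e6 & end(win) <= 2e6
    expect_true(all(th[winInside] == 0, na.rm = TRUE))
    # other breeds byte-identical
    expect_identical(genotypes(swept)[, breeds(pan) != "B1"],
                     genotypes(pan)[, breeds(pan) != "B1"])
    # loci outside untouched for everyone
    expect_identical(genotypes(swept)[!inside, ], genotypes(pan)[!inside, ])
    # haplotype sums still match dosages (panel validity)
    expect_true(validObject(swept))
    # empty region is fatal
    expect_error(plantSweep(pan, "B1", "sim1", 2, 3), "no SNP")
})

test_that("trait simulation follows the frequency-plus-noise model", {
    pan <- randomPanel(nBreeds = 5L, nPer = 4L, L = 20L, seed = 51)
    tr0 <- simulateTraitPanel(pan, causalLocus = 3L, effect = 1,
                              noiseSd = 0, seed = 1L)
    fr <- breedFrequencies(pan)
    expect_equal(unname(traitValues(tr0)[colnames(freqB(fr))]),
                 unname(freqB(fr)[3L, ]))
    # zero effect: pure noise, reproducible under the seed
    tr1 <- simulateTraitPanel(pan, 3L, effect = 0, noiseSd = 1, seed = 2L)
    tr2 <- simulateTraitPanel(pan, 3L, effect = 0, noiseSd = 1, seed = 2L)
    expect_identical(traitValues(tr1), traitValues(tr2))
})

test_that("null region length catalogue is complete and deterministic", {
    model <- testModel()
    bt <- testBreeds(3L, 6L)
    segs <- data.frame(lengthBp = c(4e6, 4e6), chromClass = "autosome")
    n1 <- nullRegionLengths(model, bt, segs, nReplicates = 2L, seed = 61L,
                            spacingBp = 13046)
    for (st in c("si", "di")) for (b in bt$name) {
        expect_false(is.null(nullLengths(n1, st, b)))
        expect_gt(length(nullLengths(n1, st, b)), 0L)
    }
    n2 <- nullRegionLengths(model, bt, segs, nReplicates = 2L, seed = 61L,
                            spacingBp = 13046)
    expect_identical(n1@lengths, n2@lengths)
    # neutral nulls are dominated by short regions: no excess of >1 Mb
    allLen <- unlist(n1@lengths)
    expect_lt(mean(allLen > 1e6), 0.05)
})

test_that("non-recombining X segments simulate with their own scaling", {
    model <- testModel()
    bt <- testBreeds(2L, 6L)
    segs <- data.frame(lengthBp = c(1e6, 1e6),
                       chromClass = c("autosome", "X_nonrec"))
    pan <- simulateNeutralPanel(model, bt, segs, seed = 81L)
    cls <- chromClass(pan)
    expect_setequal(unique(cls), c("autosome", "X_nonrec"))
    # X windows are standardized apart from autosomes in the scan
    pan2 <- ascertainmentMatch(pan, spacingBp = 5000, seed = 81L)
    fr <- breedFrequencies(pan2)
    win <- makeWindows(pan2, 100000L, 50000L, 2L)
    tr <- siScan(fr, win)
    mom <- as.data.frame(pairMoments(tr))
    expect_setequal(unique(mom$chromClass), c("auto", "X_nonrec"))
})

test_that("segment-wise ascertained simulation yields a thinned panel", {
    model <- testModel()
    bt <- testBreeds(2L, 5L)
    segs <- data.frame(lengthBp = rep(2e6, 2), chromClass = "autosome")
    pan <- simulateAscertainedPanel(model, bt, segs, seed = 91L,
                                    spacingBp = 10000)
    expect_s4_class(pan, "GenotypePanel")
    expect_true(isPhased(pan))
    expect_setequal(unique(as.character(seqnames(rowRanges(pan)))),
                    c("sim1", "sim2"))
    spacing <- sum(segs$lengthBp) / nrow(pan)
    expect_lt(abs(spacing - 10000) / 10000, 0.15)
    # deterministic under the seed
    pan2 <- simulateAscertainedPanel(model, bt, segs, seed = 91L,
                                     spacingBp = 10000)
    expect_identical(genotypes(pan), genotypes(pan2))
})
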