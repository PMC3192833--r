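#' Demographic model constructor
#'
#' Defaults encode the breed-formation model: a wolf ancestor of diploid
#' effective size 22,600 shrinking to 5,650 at domestication 5,000
#' generations ago, with all breeds splitting off simultaneously 100
#' generations ago; mutation rate 1e-8 per bp per generation, generation
#' time 3 years. Per-breed bottleneck strength is supplied separately as a
#' fraction `f` of `neWolf` (grid 0.001-0.03 in the fitting routine).
#'
#' @param neWolf,neDog,tDom,tBreed,mu,recombRate,generationYears,xNeRatio
#'   see [DemographicModel-class]
#' @export
demographicModel <- function(neWolf = 22600, neDog = 5650, tDom = 5000,
                             tBreed = 100, mu = 1e-8, recombRate = 1e-8,
                             generationYears = 3, xNeRatio = 9134 / 7752) {
    new("DemographicModel", neWolf = neWolf, neDog = neDog, tDom = tDom,
        tBreed = tBreed, mu = mu, recombRate = recombRate,
        generationYears = generationYears, xNeRatio = xNeRatio)
}

.pythonBin <- function() {
    p <- getOption("sweepscan.python", Sys.which("python"))
    if (!nzchar(p)) stop("no python interpreter found for the coalescent engine")
    p
}

# run a batch of coalescent tasks through the bundled msprime driver;
# returns a named list of list(pos=, haps=) keyed by task id
.runCoalescent <- function(tasks) {
    dir <- tempfile("coal")
    dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE), add = TRUE)
    payload <- list(out_dir = dir, tasks = tasks)
    json <- file.path(dir, "tasks.json")
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA)
    script <- system.file("python", "coalescent_panel.py",
                          package = "SweepScan", mustWork = TRUE)
    status <- system2(.pythonBin(), c(shQuote(script), shQuote(json)),
                      stdout = "", stderr = "")
    if (status != 0L)
        stop("coalescent engine failed (exit ", status, "); tasks: ",
             jsonlite::toJSON(payload$tasks, auto_unbox = TRUE))
    out <- list()
    for (t in tasks) {
        f <- file.path(dir, paste0(t$id, ".bin"))
        con <- file(f, "rb")
        hdr <- readBin(con, "integer", 2L, size = 4L, endian = "little")
        pos <- readBin(con, "double", hdr[1L], size = 8L, endian = "little")
        g <- readBin(con, "integer", hdr[1L] * hdr[2L], size = 1L,
                     signed = FALSE, endian = "little")
        close(con)
        if (hdr[1L] == 0L)
            stop("zero segregating sites for task ", t$id,
                 " (length=", t$length, ", seed=", t$seed, ")")
        out[[t$id]] <- list(pos = as.integer(pos),
                            haps = matrix(as.integer(g), nrow = hdr[1L],
                                          byrow = TRUE))
    }
    out
}

.breedTaskBits <- function(model, breedTable, segment, seed, chromClass) {
    scale <- if (chromClass == "X_nonrec") model@xNeRatio * 0.75 else 1
    list(n_per_pop = I(as.integer(breedTable$n)),
         pop_f = I(as.numeric(breedTable$f)),
         ne_wolf = model@neWolf, ne_dog = model@neDog,
         t_dom = model@tDom, t_breed = model@tBreed,
         mu = model@mu, recomb = model@recombRate,
         length = segment, size_scale = scale, seed = seed)
}

# derive a stream of engine seeds below 2^31 from one user seed
.seedStream <- function(seed, n) {
    set.seed(seed)
    sample.int(2000000000L, n)
}

#' Simulate a neutral multi-breed panel
#'
#' Coalescent simulation (msprime as the sampler) under the demographic
#' program of [demographicModel]: wolf ancestor, instantaneous size change
#' to `neDog` at `tDom`, simultaneous split into breed populations of size
#' `f * neWolf` at `tBreed`, present-day sampling. Segments are simulated
#' independently and concatenated as chromosomes `sim1`, `sim2`, ...
#' Non-recombining-X segments scale all population sizes by
#' `xNeRatio * 3/4`. Output is phased and free of missingness; all samples
#' are recorded as female.
#'
#' @param model a [DemographicModel-class]
#' @param breedTable data.frame with columns `name`, `n` (diploid samples)
#'   and `f` (bottleneck fraction of `neWolf`)
#' @param segments data.frame with columns `lengthBp` and `chromClass`
#' @param seed integer seed; same seed, same panel
#' @return a phased [GenotypePanel-class]
#' @export
simulateNeutralPanel <- function(model, breedTable,
                                 segments = data.frame(
                                     lengthBp = 5e6, chromClass = "autosome"),
                                 seed = 1L) {
    stopifnot(nrow(segments) >= 1L)
    seeds <- .seedStream(seed, nrow(segments))
    tasks <- lapply(seq_len(nrow(segments)), function(k) {
        c(list(id = paste0("seg", k)),
          .breedTaskBits(model, breedTable, segments$lengthBp[k], seeds[k],
                         segments$chromClass[k]))
    })
    sims <- .runCoalescent(tasks)
    .panelFromSims(sims, breedTable, segments)
}

.panelFromSims <- function(sims, breedTable, segments) {
    nS <- sum(breedTable$n)
    hapAList <- hapBList <- posList <- chromList <- clsList <- list()
    for (k in seq_along(sims)) {
        s <- sims[[k]]
        sims[[k]] <- list()       # release the raw segment as we go
        hapAList[[k]] <- s$haps[, seq(1L, 2L * nS, 2L), drop = FALSE]
        hapBList[[k]] <- s$haps[, seq(2L, 2L * nS, 2L), drop = FALSE]
        posList[[k]] <- s$pos
        chromList[[k]] <- rep(paste0("sim", k), length(s$pos))
        clsList[[k]] <- rep(segments$chromClass[k], length(s$pos))
    }
    hapA <- do.call(rbind, hapAList); hapB <- do.call(rbind, hapBList)
    rm(hapAList, hapBList)
    loci <- GRanges(unlist(chromList),
                    IRanges(unlist(posList), width = 1L),
                    alleleA = "A", alleleB = "B",
                    chromClass = unlist(clsList))
    breed <- rep(breedTable$name, breedTable$n)
    ids <- paste0(breed, "_", unlist(lapply(breedTable$n, seq_len)))
    GenotypePanel(hapA + hapB, loci, breed = breed,
                  sex = rep("F", nS), hapA = hapA, hapB = hapB,
                  sampleIds = ids)
}

#' Simulate an ascertainment-matched panel segment by segment
#'
#' Memory-frugal driver for large panels: each segment is simulated
#' ([simulateNeutralPanel]) and immediately ascertainment-matched and
#' thinned ([ascertainmentMatch]) before the next one starts, so the
#' full-density genotype matrices of at most one segment are ever held.
#' Segments are independent coalescent samples, and the frequency
#' histogram is matched per segment, which is distributionally identical
#' to matching the concatenated panel.
#'
#' @inheritParams simulateNeutralPanel
#' @inheritParams ascertainmentMatch
#' @return a phased, thinned [GenotypePanel-class]
#' @export
simulateAscertainedPanel <- function(model, breedTable, segments, seed = 1L,
                                     targetHist = rep(1, 10),
                                     spacingBp = 13046) {
    segSeeds <- .seedStream(seed, nrow(segments))
    parts <- vector("list", nrow(segments))
    for (k in seq_len(nrow(segments))) {
        sub <- simulateNeutralPanel(model, breedTable, segments[k, ],
                                    seed = segSeeds[k])
        sub <- ascertainmentMatch(sub, targetHist = targetHist,
                                  spacingBp = spacingBp,
                                  seed = segSeeds[k])
        rr <- rowRanges(sub)
        GenomeInfoDb::seqlevels(rr) <- paste0("sim", k)
        rowRanges(sub) <- rr
        parts[[k]] <- sub
    }
    # segments are disjoint chromosomes; rbind warns about the lack of
    # shared seqlevels, which is exactly the intended layout
    suppressWarnings(do.call(rbind, parts))
}

#' Match a panel to a target allele-frequency spectrum and marker density
#'
#' Emulates array-ascertainment bias by rejection-sampling sites so the
#' pooled minor-allele-frequency histogram matches `targetHist`, then thins
#' to an average inter-marker spacing of `spacingBp` (uniform random
#' subset, preserving order and phasing). The default target is uniform
#' over ten MAF bins on (0, 0.5], the flattened spectrum characteristic of
#' array SNP panels. Infeasible targets (empty donor bins) are served
#' best-effort with a reported deficit.
#'
#' @param panel a [GenotypePanel-class]
#' @param targetHist numeric vector of bin masses over `breaks` (needs not
#'   sum to 1)
#' @param breaks MAF bin breaks on `[0, 0.5]`
#' @param spacingBp target average spacing (one marker every 13,046 bp by
#'   default)
#' @param seed RNG seed
#' @return the thinned [GenotypePanel-class]
#' @export
ascertainmentMatch <- function(panel, targetHist = rep(1, 10),
                               breaks = seq(0, 0.5, length.out = 11),
                               spacingBp = 13046, seed = 1L) {
    set.seed(seed)
    g <- genotypes(panel)
    maf <- pmin(rowMeans(g) / 2, 1 - rowMeans(g) / 2)
    bin <- cut(maf, breaks, include.lowest = FALSE, labels = FALSE)
    keepable <- !is.na(bin)               # drops monomorphic/out-of-range
    donor <- tabulate(bin[keepable], length(targetHist))
    target <- targetHist / sum(targetHist)
    # retention probability per bin, scaled so the best-covered bin keeps all
    ratio <- ifelse(donor > 0, target / (donor / sum(donor)), 0)
    prob <- ratio / max(ratio[donor > 0])
    if (any(target > 0 & donor == 0))
        message("ascertainmentMatch: empty donor bin(s) ",
                paste(which(target > 0 & donor == 0), collapse = ","),
                "; matching is best-effort")
    keep <- keepable & runif(nrow(g)) < prob[bin]
    idx <- which(keep)
    # thin per chromosome to the target density
    rr <- rowRanges(panel)
    chrom <- as.character(seqnames(rr))
    final <- integer(0)
    for (ch in unique(chrom)) {
        onChr <- idx[chrom[idx] == ch]
        span <- max(start(rr)[chrom == ch])
        nTarget <- max(2L, round(span / spacingBp))
        if (length(onChr) > nTarget)
            onChr <- sort(sample(onChr, nTarget))
        final <- c(final, onChr)
    }
    panel[final, ]
}

#' Haplotype LD decay curve
#'
#' Mean haplotype r-squared between marker pairs separated by at most
#' `maxBp`, averaged in `binBp`-wide distance bins, pooled or within one
#' breed. Pairs with a monomorphic member are skipped.
#'
#' @param panel a phased [GenotypePanel-class]
#' @param maxBp maximum pair separation
#' @param binBp distance bin width
#' @param breed restrict to one breed's haplotypes (default pooled)
#' @return data.frame: `bin_start`, `bin_mid`, `mean_r2`, `n_pairs`
#' @export
ldDecay <- function(panel, maxBp = 500000L, binBp = 10000L, breed = NULL) {
    stopifnot(isPhased(panel))
    H <- haplotypes(panel)
    if (!is.null(breed)) H <- H[, haplotypeBreeds(panel) == breed,
                                drop = FALSE]
    rr <- rowRanges(panel)
    chrom <- as.character(seqnames(rr)); pos <- start(rr)
    nBins <- ceiling(maxBp / binBp)
    sums <- counts <- numeric(nBins)
    p <- rowMeans(H)
    polym <- p > 0 & p < 1
    for (ch in unique(chrom)) {
        sel <- which(chrom == ch & polym)
        if (length(sel) < 2L) next
        X <- H[sel, , drop = FALSE]
        ps <- p[sel]; xs <- pos[sel]
        L <- length(sel)
        for (lag in seq_len(L - 1L)) {
            i <- seq_len(L - lag); j <- i + lag
            d <- xs[j] - xs[i]
            ok <- d <= maxBp
            if (!any(ok)) break
            i <- i[ok]; j <- j[ok]; d <- d[ok]
            pab <- rowMeans(X[i, , drop = FALSE] * X[j, , drop = FALSE])
            r2 <- (pab - ps[i] * ps[j])^2 /
                (ps[i] * (1 - ps[i]) * ps[j] * (1 - ps[j]))
            b <- pmin(ceiling(d / binBp), nBins)
            sums <- sums + unname(tapply(r2, factor(b, seq_len(nBins)), sum,
                                         default = 0))
            counts <- counts + tabulate(b, nBins)
        }
    }
    data.frame(bin_start = (seq_len(nBins) - 1L) * binBp,
               bin_mid = (seq_len(nBins) - 0.5) * binBp,
               mean_r2 = ifelse(counts > 0, sums / counts, NA_real_),
               n_pairs = counts)
}

#' Fit a breed bottleneck size from LD decay
#'
#' Simulates a single-breed panel for every bottleneck fraction on the
#' grid (all grid points in one engine batch, segment seeds shared across
#' grid points for variance reduction), applies the same
#' ascertainment/thinning protocol as the observed curve, computes the LD
#' decay curve and returns the grid value minimizing the least-squares
#' distance to the observed curve. Ties break toward the smaller `f`.
#'
#' @param observed data.frame from [ldDecay] (>= 10 populated bins)
#' @param model a [DemographicModel-class]
#' @param grid candidate bottleneck fractions (59-point default
#'   0.001-0.03 step 0.0005)
#' @param nSamples diploid sample count of the simulated breed
#' @param segments segment table as in [simulateNeutralPanel]
#' @param seed RNG seed
#' @param spacingBp,targetHist ascertainment protocol (must match the
#'   observed panel's)
#' @return list: `f` (best grid value), `ss` (per-grid sum of squares),
#'   `grid`
#' @export
fitBottleneck <- function(observed, model,
                          grid = seq(0.001, 0.03, by = 0.0005),
                          nSamples = 10L,
                          segments = data.frame(lengthBp = 5e6,
                                                chromClass = "autosome"),
                          seed = 1L, spacingBp = 13046,
                          targetHist = rep(1, 10)) {
    if (length(grid) == 0L) stop("empty grid")
    if (sum(!is.na(observed$mean_r2) & observed$n_pairs > 0) < 10L)
        stop("observed curve needs >= 10 populated bins")
    segSeeds <- .seedStream(seed, nrow(segments))
    tasks <- list()
    for (gi in seq_along(grid)) for (k in seq_len(nrow(segments))) {
        tasks[[length(tasks) + 1L]] <- c(
            list(id = paste0("f", gi, "_s", k)),
            .breedTaskBits(model,
                           data.frame(name = "B", n = nSamples, f = grid[gi]),
                           segments$lengthBp[k], segSeeds[k] + gi,
                           segments$chromClass[k]))
    }
    sims <- .runCoalescent(tasks)
    maxBp <- max(observed$bin_start) + (observed$bin_mid[1] -
                                        observed$bin_start[1]) * 2
    binBp <- observed$bin_mid[1] * 2
    ss <- numeric(length(grid))
    bt <- data.frame(name = "B", n = nSamples, f = NA)
    for (gi in seq_along(grid)) {
        sub <- sims[paste0("f", gi, "_s", seq_len(nrow(segments)))]
        pan <- .panelFromSims(sub, bt, segments)
        pan <- ascertainmentMatch(pan, targetHist = targetHist,
                                  spacingBp = spacingBp, seed = seed + gi)
        cur <- ldDecay(pan, maxBp = maxBp, binBp = binBp)
        ok <- !is.na(observed$mean_r2) & !is.na(cur$mean_r2)
        ss[gi] <- sum((observed$mean_r2[ok] - cur$mean_r2[ok])^2)
    }
    list(f = grid[which.min(ss)], ss = ss, grid = grid)
}

#' Plant a fixed-haplotype sweep into a breed
#'
#' Copies one randomly chosen haplotype of the breed over `[start, end]`
#' into every haplotype of every sample of that breed, emulating complete
#' fixation of a selected haplotype. Other breeds and loci outside the
#' region are untouched.
#'
#' @param panel a phased [GenotypePanel-class]
#' @param breed target breed
#' @param chrom,start,end the swept interval (1-based inclusive)
#' @param seed RNG seed for the donor haplotype choice
#' @return the modified panel
#' @export
plantSweep <- function(panel, breed, chrom, start, end, seed = 1L) {
    rr <- rowRanges(panel)
    inRegion <- which(as.logical(seqnames(rr) == chrom) &
                      BiocGenerics::start(rr) >= start &
                      BiocGenerics::start(rr) <= end)
    if (length(inRegion) == 0L) stop("planted region contains no SNP")
    cols <- which(breeds(panel) == breed)
    if (length(cols) == 0L) stop("breed not in panel: ", breed)
    set.seed(seed)
    donorSample <- sample(cols, 1L)
    donorSide <- sample(c("hapA", "hapB"), 1L)
    donor <- assay(panel, donorSide)[inRegion, donorSample]
    a <- assay(panel, "hapA"); b <- assay(panel, "hapB")
    a[inRegion, cols] <- donor
    b[inRegion, cols] <- donor
    g <- a + b
    assays(panel) <- list(geno = g, hapA = a, hapB = b)
    panel
}

#' Simulate a breed trait controlled by one causal locus
#'
#' Breed phenotype = `effect` x breed B-allele frequency at the causal
#' locus + Gaussian noise.
#'
#' @param panel a [GenotypePanel-class]
#' @param causalLocus row index of the causal SNP
#' @param effect per-allele breed-mean shift
#' @param noiseSd phenotype noise standard deviation
#' @param seed RNG seed
#' @return a quantitative [TraitTable-class]
#' @export
simulateTraitPanel <- function(panel, causalLocus, effect, noiseSd,
                               seed = 1L) {
    set.seed(seed)
    fr <- breedFrequencies(panel)
    f <- fr@freqB[causalLocus, ]
    vals <- effect * f + rnorm(length(f), 0, noiseSd)
    TraitTable(setNames(vals, colnames(fr@freqB)),
               coding = "quantitative", trait = "simulated")
}

#' Null distribution of sweep-region lengths from neutral replicates
#'
#' For each replicate: simulate a neutral panel, ascertainment-match and
#' thin it, run the identical S_i and d_i scans (same window geometry and
#' tail fraction as the analysis panels), merge flagged windows into
#' regions and pool their lengths per breed and statistic. Failed
#' replicates are skipped with a report.
#'
#' @param model a [DemographicModel-class]
#' @param breedTable,segments as in [simulateNeutralPanel]
#' @param nReplicates neutral replicates
#' @param seed master seed (full determinism: same seed, same object)
#' @param windowBp,stepBp,minSnps,tailFrac scan parameters; must equal the
#'   analysis scan's
#' @param spacingBp,targetHist ascertainment protocol
#' @param statistics which scans to run
#' @return a [NullLengthDistribution-class]
#' @export
nullRegionLengths <- function(model, breedTable, segments, nReplicates = 10L,
                              seed = 1L, windowBp = 150000L, stepBp = 25000L,
                              minSnps = 5L, tailFrac = 0.01,
                              spacingBp = 13046, targetHist = rep(1, 10),
                              statistics = c("si", "di")) {
    repSeeds <- .seedStream(seed, nReplicates)
    lens <- lapply(statistics, function(s)
        setNames(vector("list", nrow(breedTable)), breedTable$name))
    names(lens) <- statistics
    failed <- 0L
    for (rep in seq_len(nReplicates)) {
        res <- tryCatch({
            pan <- simulateNeutralPanel(model, breedTable, segments,
                                        seed = repSeeds[rep])
            pan <- ascertainmentMatch(pan, targetHist = targetHist,
                                      spacingBp = spacingBp,
                                      seed = repSeeds[rep])
            fr <- breedFrequencies(pan)
            win <- makeWindows(pan, windowBp, stepBp, minSnps)
            out <- list()
            if ("si" %in% statistics) {
                tr <- siScan(fr, win)
                out$si <- mergeToRegions(tr, tailWindows(tr, tailFrac))
            }
            if ("di" %in% statistics) {
                tr <- diScan(fr, win)
                out$di <- mergeToRegions(tr, tailWindows(tr, tailFrac))
            }
            out
        }, error = function(e) e)
        if (inherits(res, "error")) {
            failed <- failed + 1L
            message("null replicate ", rep, " failed: ",
                    conditionMessage(res))
            next
        }
        for (s in statistics) {
            reg <- res[[s]]
            for (b in breedTable$name)
                lens[[s]][[b]] <- c(lens[[s]][[b]],
                                    reg$length_bp[reg$breed == b])
        }
    }
    if (failed > 0L)
        message("nullRegionLengths: ", failed, "/", nReplicates,
                " replicates failed")
    NullLengthDistribution(lens,
        descriptor = list(seed = seed, nReplicates = nReplicates,
                          failed = failed, windowBp = windowBp,
                          stepBp = stepBp, minSnps = minSnps,
                          tailFrac = tailFrac, spacingBp = spacingBp))
}
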