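#' Read a breed-labelled genotype panel
#'
#' Reads diploid biallelic SNP genotypes from VCF 4.x (via \pkg{vcfR}) or
#' PLINK transposed text (`.tped`/`.tfam`). Breed labels come from the
#' sample-metadata TSV for VCF input (columns `sample_id`, `breed`, `sex`)
#' and from the family-ID column of the `.tfam` for PLINK input.
#' Multiallelic sites and sites with only missing calls are dropped with a
#' reported count; loci are sorted within chromosome.
#'
#' @param path the `.vcf`/`.vcf.gz` file, or the common prefix of a
#'   `.tped`/`.tfam` pair.
#' @param format `"vcf"` or `"tped"`.
#' @param sampleMeta for VCF input: a data.frame with `sample_id`, `breed`
#'   and optionally `sex`, or the path of such a TSV. Defaults to
#'   `<path>.samples.tsv` when that file exists.
#' @param chromClass either a single class for all loci, or a data.frame
#'   with columns `chrom`, `start`, `end`, `class` mapping intervals to
#'   \{autosome, PAR, X_nonrec\}.
#' @return a [GenotypePanel-class]; phased assays are populated when every
#'   genotype in a VCF uses the `|` separator.
#' @importClassesFrom vcfR vcfR
#' @export
readPanel <- function(path, format = c("vcf", "tped"), sampleMeta = NULL,
                      chromClass = "autosome") {
    format <- match.arg(format)
    if (format == "vcf") .readVcfPanel(path, sampleMeta, chromClass)
    else .readTpedPanel(path, chromClass)
}

.lociClass <- function(chrom, pos, chromClass) {
    if (is.character(chromClass) && length(chromClass) == 1L)
        return(rep(chromClass, length(pos)))
    cls <- rep("autosome", length(pos))
    for (k in seq_len(nrow(chromClass))) {
        hit <- chrom == chromClass$chrom[k] & pos >= chromClass$start[k] &
            pos <= chromClass$end[k]
        cls[hit] <- chromClass$class[k]
    }
    cls
}

.panelFromParts <- function(chrom, pos, alleleA, alleleB, geno, hapA, hapB,
                            sampleIds, breed, sex, chromClass) {
    o <- order(factor(chrom, levels = unique(chrom)), pos)
    chrom <- chrom[o]; pos <- pos[o]
    alleleA <- alleleA[o]; alleleB <- alleleB[o]
    geno <- geno[o, , drop = FALSE]
    if (!is.null(hapA)) { hapA <- hapA[o, , drop = FALSE]
                          hapB <- hapB[o, , drop = FALSE] }
    if (anyDuplicated(paste(chrom, pos)))
        stop("duplicated locus positions after sorting")
    loci <- GRanges(chrom, IRanges(pos, width = 1L),
                    alleleA = alleleA, alleleB = alleleB,
                    chromClass = .lociClass(chrom, pos, chromClass))
    GenotypePanel(geno, loci, breed = breed, sex = sex, hapA = hapA,
                  hapB = hapB, sampleIds = sampleIds)
}

.readVcfPanel <- function(path, sampleMeta, chromClass) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    gt <- vcf@gt
    sampleIds <- colnames(gt)[-1L]
    if (anyDuplicated(sampleIds))
        stop("duplicated sample id in VCF: ",
             paste(sampleIds[duplicated(sampleIds)], collapse = ", "))
    if (is.null(sampleMeta)) {
        guess <- paste0(path, ".samples.tsv")
        if (file.exists(guess)) sampleMeta <- guess
        else stop("sampleMeta (sample_id/breed TSV) is required for VCF input")
    }
    if (is.character(sampleMeta))
        sampleMeta <- read.table(sampleMeta, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
    m <- match(sampleIds, sampleMeta$sample_id)
    if (anyNA(m))
        stop("samples missing from metadata: ",
             paste(sampleIds[is.na(m)], collapse = ", "))
    breed <- sampleMeta$breed[m]
    sex <- if ("sex" %in% colnames(sampleMeta)) sampleMeta$sex[m] else NULL

    multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"]) | fix[, "ALT"] == "."
    gtf <- sub(":.*", "", gt[, -1L, drop = FALSE])   # GT is the leading field
    gtf[is.na(gtf)] <- "./."                         # vcfR reads ./. as NA
    phasedSep <- matrix(grepl("|", gtf, fixed = TRUE), nrow(gtf))
    bad <- matrix(!grepl("^(\\.|[0-9]+)([/|](\\.|[0-9]+))?$", gtf),
                  nrow(gtf))
    if (any(bad)) {
        idx <- which(bad, arr.ind = TRUE)[1L, ]
        stop("malformed genotype at record ", idx[1L], ", sample ",
             sampleIds[idx[2L]])
    }
    a1 <- sub("[/|].*", "", gtf); a2 <- sub(".*[/|]", "", gtf)
    toInt <- function(x) { x[x == "."] <- NA; matrix(as.integer(x), nrow(gtf)) }
    a1 <- toInt(a1); a2 <- toInt(a2)
    geno <- a1 + a2
    allMissing <- rowSums(!is.na(geno)) == 0L
    drop <- multi | allMissing
    if (any(drop))
        message("readPanel: dropping ", sum(multi), " multiallelic and ",
                sum(allMissing & !multi), " all-missing site(s)")
    keep <- !drop
    phased <- all(phasedSep[keep, , drop = FALSE] |
                  is.na(geno[keep, , drop = FALSE]))
    .panelFromParts(
        chrom = fix[keep, "CHROM"], pos = as.integer(fix[keep, "POS"]),
        alleleA = fix[keep, "REF"], alleleB = fix[keep, "ALT"],
        geno = geno[keep, , drop = FALSE],
        hapA = if (phased) a1[keep, , drop = FALSE],
        hapB = if (phased) a2[keep, , drop = FALSE],
        sampleIds = sampleIds, breed = breed, sex = sex,
        chromClass = chromClass)
}

.readTpedPanel <- function(path, chromClass) {
    tped <- paste0(path, ".tped"); tfam <- paste0(path, ".tfam")
    fam <- read.table(tfam, header = FALSE, stringsAsFactors = FALSE)
    sampleIds <- fam[[2L]]
    if (anyDuplicated(sampleIds))
        stop("duplicated sample id in tfam: ",
             paste(sampleIds[duplicated(sampleIds)], collapse = ", "))
    breed <- fam[[1L]]
    sex <- c("1" = "M", "2" = "F")[as.character(fam[[5L]])]
    lines <- readLines(tped)
    nS <- length(sampleIds)
    want <- 4L + 2L * nS
    toks <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(toks)
    if (any(nf != want))
        stop("malformed tped record at line ", which(nf != want)[1L],
             " (expected ", want, " fields, got ", nf[nf != want][1L], ")")
    tm <- matrix(unlist(toks), nrow = length(toks), byrow = TRUE)
    chrom <- tm[, 1L]; pos <- as.integer(tm[, 4L])
    al <- tm[, -(1:4), drop = FALSE]
    a1 <- al[, seq(1L, 2L * nS, 2L), drop = FALSE]
    a2 <- al[, seq(2L, 2L * nS, 2L), drop = FALSE]
    geno <- matrix(NA_integer_, nrow(tm), nS)
    alleleA <- alleleB <- character(nrow(tm))
    multi <- allMissing <- logical(nrow(tm))
    for (i in seq_len(nrow(tm))) {
        obs <- c(a1[i, ], a2[i, ])
        lv <- sort(unique(obs[obs != "0"]))
        if (length(lv) > 2L) { multi[i] <- TRUE; next }
        if (length(lv) == 0L) { allMissing[i] <- TRUE; next }
        alleleA[i] <- lv[1L]
        alleleB[i] <- if (length(lv) == 2L) lv[2L] else "."
        b1 <- ifelse(a1[i, ] == "0", NA_integer_,
                     as.integer(a1[i, ] == alleleB[i]))
        b2 <- ifelse(a2[i, ] == "0", NA_integer_,
                     as.integer(a2[i, ] == alleleB[i]))
        geno[i, ] <- b1 + b2
    }
    drop <- multi | allMissing
    if (any(drop))
        message("readPanel: dropping ", sum(multi), " multiallelic and ",
                sum(allMissing), " all-missing site(s)")
    keep <- !drop
    .panelFromParts(chrom = chrom[keep], pos = pos[keep],
                    alleleA = alleleA[keep], alleleB = alleleB[keep],
                    geno = geno[keep, , drop = FALSE], hapA = NULL,
                    hapB = NULL, sampleIds = sampleIds, breed = breed,
                    sex = sex, chromClass = chromClass)
}

#' Write a genotype panel
#'
#' VCF output is written through \pkg{vcfR} (gzipped when `path` ends in
#' `.gz`) with a `<path>.samples.tsv` sidecar carrying breed and sex; PLINK
#' output writes `<path>.tped` + `<path>.tfam` with breed as family ID.
#' `writePanel` and [readPanel] round-trip genotypes, loci and breeds.
#'
#' @param panel a [GenotypePanel-class]
#' @param path output file (VCF) or prefix (tped)
#' @param format `"vcf"` or `"tped"`
#' @return `path`, invisibly
#' @export
writePanel <- function(panel, path, format = c("vcf", "tped")) {
    format <- match.arg(format)
    rr <- rowRanges(panel)
    g <- genotypes(panel)
    if (format == "vcf") {
        if (isPhased(panel)) {
            a <- assay(panel, "hapA"); b <- assay(panel, "hapB")
            gt <- matrix(paste(a, b, sep = "|"), nrow(g))
        } else {
            gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow(g))
        }
        gt[is.na(g)] <- "./."
        gt <- cbind(FORMAT = "GT", gt)
        colnames(gt) <- c("FORMAT", colnames(panel))
        fix <- cbind(CHROM = as.character(seqnames(rr)),
                     POS = as.character(start(rr)),
                     ID = paste0("snp", seq_along(rr)),
                     REF = mcols(rr)$alleleA, ALT = mcols(rr)$alleleB,
                     QUAL = ".", FILTER = "PASS", INFO = ".")
        out <- new("vcfR", meta = c("##fileformat=VCFv4.2",
                                    "##source=SweepScan"),
                   fix = fix, gt = gt)
        vcfR::write.vcf(out, file = path)
        meta <- data.frame(sample_id = colnames(panel), breed = breeds(panel),
                           sex = colData(panel)$sex)
        write.table(meta, paste0(path, ".samples.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    } else {
        nS <- ncol(g)
        aA <- mcols(rr)$alleleA; aB <- mcols(rr)$alleleB
        al1 <- al2 <- matrix("0", nrow(g), nS)
        is01 <- !is.na(g) & g <= 1L; is2 <- !is.na(g) & g == 2L
        is0 <- !is.na(g) & g == 0L; is12 <- !is.na(g) & g >= 1L
        al1[is01] <- rep(aA, nS)[is01]
        al1[is2] <- rep(aB, nS)[is2]
        al2[is0] <- rep(aA, nS)[is0]
        al2[is12] <- rep(aB, nS)[is12]
        inter <- matrix("", nrow(g), 2L * nS)
        inter[, seq(1L, 2L * nS, 2L)] <- al1
        inter[, seq(2L, 2L * nS, 2L)] <- al2
        tped <- cbind(as.character(seqnames(rr)),
                      paste0("snp", seq_along(rr)), "0",
                      as.character(start(rr)), inter)
        write.table(tped, paste0(path, ".tped"), quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
        sexCode <- c(M = 1L, F = 2L)[as.character(colData(panel)$sex)]
        sexCode[is.na(sexCode)] <- 0L
        fam <- data.frame(breeds(panel), colnames(panel), 0L, 0L, sexCode,
                          -9L)
        write.table(fam, paste0(path, ".tfam"), quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
    }
    invisible(path)
}

#' Export genomic regions as BED with a statistics sidecar
#'
#' BED uses 0-based half-open coordinates; every metadata column of `gr` is
#' written to a `<path>.tsv` sidecar alongside 1-based coordinates.
#'
#' @param gr a `GRanges` (e.g. candidate sweep regions)
#' @param path output BED path
#' @export
writeRegionsBed <- function(gr, path) {
    name <- if (!is.null(mcols(gr)$breed)) mcols(gr)$breed
            else rep(".", length(gr))
    bed <- data.frame(chrom = as.character(seqnames(gr)),
                      start = start(gr) - 1L, end = end(gr), name = name)
    write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    side <- cbind(data.frame(chrom = as.character(seqnames(gr)),
                             start = start(gr), end = end(gr)),
                  as.data.frame(mcols(gr)))
    write.table(side, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
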