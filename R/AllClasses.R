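#' @import methods GenomicRanges SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<- queryHits subjectHits
#' @importFrom IRanges IRanges findOverlaps
#' @importFrom BiocGenerics start end width strand
#' @importFrom stats sd var rnorm runif setNames p.adjust pf cor complete.cases
#' @importFrom utils read.table write.table head tail
NULL

#' GenotypePanel: breed-labelled SNP genotypes with optional phased haplotypes
#'
#' The universal input container of the package. A `GenotypePanel` extends
#' [SummarizedExperiment::RangedSummarizedExperiment]: rows are biallelic loci
#' (a [GenomicRanges::GRanges] of width-1 positions carrying `alleleA`,
#' `alleleB` and `chromClass` metadata columns), columns are samples with
#' `breed` and `sex` in `colData`, and the `"geno"` assay stores the per
#' sample B-allele dosage in \{0, 1, 2, NA\}. Phased panels additionally carry
#' `"hapA"`/`"hapB"` 0/1 assays whose sum reproduces the dosage at every
#' non-missing site.
#'
#' `chromClass` is one of `"autosome"`, `"PAR"`, `"X_nonrec"`; autosomes and
#' the pseudo-autosomal region are pooled by downstream scans while the
#' non-recombining X is standardized separately.
#'
#' @slot .. see [SummarizedExperiment::RangedSummarizedExperiment]
#' @aliases GenotypePanel-class
#' @export
setClass("GenotypePanel", contains = "RangedSummarizedExperiment")

.validGenotypePanel <- function(object) {
    msg <- NULL
    if (!"geno" %in% assayNames(object))
        msg <- c(msg, "assay 'geno' is required")
    cd <- colData(object)
    if (!"breed" %in% colnames(cd))
        msg <- c(msg, "colData must contain a 'breed' column")
    else if (any(is.na(cd$breed) | cd$breed == ""))
        msg <- c(msg, "every sample needs a non-empty breed label")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicated sample ids")
    rr <- rowRanges(object)
    if (length(rr)) {
        if (!all(c("alleleA", "alleleB", "chromClass") %in% colnames(mcols(rr))))
            msg <- c(msg, "rowRanges must carry alleleA, alleleB, chromClass")
        else if (!all(mcols(rr)$chromClass %in% c("autosome", "PAR", "X_nonrec")))
            msg <- c(msg, "chromClass must be autosome, PAR or X_nonrec")
        bad <- vapply(split(start(rr), as.character(seqnames(rr))),
                      function(p) is.unsorted(p, strictly = TRUE), logical(1))
        if (any(bad))
            msg <- c(msg, "loci must be strictly increasing within chromosome")
    }
    g <- assay(object, "geno")
    rng <- suppressWarnings(range(g, na.rm = TRUE))  # cheap on huge panels
    if (length(g) && is.finite(rng[1L]) && (rng[1L] < 0L || rng[2L] > 2L))
        msg <- c(msg, "genotypes must be B-allele dosages in {0,1,2,NA}")
    if (all(c("hapA", "hapB") %in% assayNames(object))) {
        hs <- assay(object, "hapA") + assay(object, "hapB")
        if (!isTRUE(all(is.na(g) | hs == g)))
            msg <- c(msg, "haplotype pair sums must equal the genotype at non-missing sites")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("GenotypePanel", .validGenotypePanel)

#' Per-breed allele frequencies and heterozygosity
#'
#' Row order follows the loci of the source panel; one column per breed.
#' `freqB` is the fraction of non-missing alleles that are the B allele
#' (`NA` where a breed has no called allele: the undefined flag), `nCalled`
#' the non-missing allele count, `hetObs` the observed fraction of
#' heterozygous individuals among called individuals (used by the
#' Weir-Cockerham estimator) and `nInd` the called-individual count.
#'
#' @slot freqB,nCalled,hetObs,nInd numeric matrices, loci x breeds
#' @slot loci GRanges of the source loci
#' @export
setClass("BreedFreq",
    representation(freqB = "matrix", nCalled = "matrix", hetObs = "matrix",
                   nInd = "matrix", loci = "GRanges"))

setValidity("BreedFreq", function(object) {
    msg <- NULL
    d <- dim(object@freqB)
    if (!identical(d, dim(object@nCalled)) || !identical(d, dim(object@nInd)))
        msg <- c(msg, "matrix dimensions disagree")
    if (length(object@loci) != d[1L])
        msg <- c(msg, "loci length must match rows")
    f <- object@freqB
    if (any(f < 0 | f > 1, na.rm = TRUE))
        msg <- c(msg, "frequencies outside [0,1]")
    if (is.null(msg)) TRUE else msg
})

#' Windowed statistic track (S_i or d_i)
#'
#' Values of one sweep statistic for every retained sliding window (rows)
#' and breed (columns), plus the pair moments used for standardization and
#' the count of defined breed pairs per window.
#'
#' @slot windows GRanges of retained windows (mcols: n_snps, chromClass)
#' @slot values windows x breeds matrix of the statistic
#' @slot statistic "si" or "di"
#' @slot moments DataFrame of pair moments (breed_i, breed_j, chromClass,
#'   expectation, sd)
#' @slot nPairs windows x breeds count of breed pairs contributing
#' @export
setClass("WindowStatTrack",
    representation(windows = "GRanges", values = "matrix",
                   statistic = "character", moments = "DataFrame",
                   nPairs = "matrix"))

setValidity("WindowStatTrack", function(object) {
    msg <- NULL
    if (nrow(object@values) != length(object@windows))
        msg <- c(msg, "values rows must match windows")
    if (!object@statistic %in% c("si", "di"))
        msg <- c(msg, "statistic must be 'si' or 'di'")
    if (is.null(msg)) TRUE else msg
})

#' Null distribution of sweep-region lengths
#'
#' Region lengths obtained by running the identical scan on neutral
#' simulated panels, catalogued per statistic and breed. Used to assign
#' marginal p-values to observed candidate regions.
#'
#' @slot lengths named list: statistic -> named list breed -> numeric lengths
#' @slot descriptor list describing the generating model and seed
#' @export
setClass("NullLengthDistribution",
    representation(lengths = "list", descriptor = "list"))

#' Demographic model for the breed-formation coalescent
#'
#' Wolf ancestor of diploid size `neWolf`, instantaneous decrease to `neDog`
#' at domestication (`tDom` generations ago), simultaneous split into breed
#' populations of size `f * neWolf` at breed formation (`tBreed` generations
#' ago), present-day sampling. `xNeRatio` rescales sizes for non-recombining
#' X segments (X/autosome effective-size ratio; on top of 3/4 chromosome
#' accounting).
#'
#' @slot neWolf,neDog diploid effective sizes
#' @slot tDom,tBreed times in generations before present
#' @slot mu mutation rate per bp per generation
#' @slot recombRate uniform recombination rate per bp per generation
#' @slot generationYears years per generation (annotation only)
#' @slot xNeRatio X-to-autosome effective-size ratio
#' @export
setClass("DemographicModel",
    representation(neWolf = "numeric", neDog = "numeric", tDom = "numeric",
                   tBreed = "numeric", mu = "numeric", recombRate = "numeric",
                   generationYears = "numeric", xNeRatio = "numeric"))

setValidity("DemographicModel", function(object) {
    msg <- NULL
    if (object@tBreed >= object@tDom)
        msg <- c(msg, "tBreed must be more recent than tDom")
    if (any(c(object@neWolf, object@neDog, object@mu, object@recombRate) <= 0))
        msg <- c(msg, "sizes and rates must be positive")
    if (is.null(msg)) TRUE else msg
})

#' Breed-level trait table for across-breed GWAS
#'
#' One phenotype value per included breed; breeds absent from the table are
#' excluded from the analysis. Quantitative traits are arbitrary numbers,
#' dichotomous traits are coded 0/1.
#'
#' @slot trait trait name
#' @slot coding "quantitative" or "dichotomous"
#' @slot values named numeric vector, names are breeds
#' @export
setClass("TraitTable",
    representation(trait = "character", coding = "character",
                   values = "numeric"))

setValidity("TraitTable", function(object) {
    msg <- NULL
    if (!object@coding %in% c("quantitative", "dichotomous"))
        msg <- c(msg, "coding must be quantitative or dichotomous")
    if (length(object@values) && is.null(names(object@values)))
        msg <- c(msg, "values must be named by breed")
    if (length(unique(object@values)) < 2L)
        msg <- c(msg, "need >=2 distinct trait values across breeds")
    if (object@coding == "dichotomous" && !all(object@values %in% c(0, 1)))
        msg <- c(msg, "dichotomous values must be 0/1")
    if (is.null(msg)) TRUE else msg
})
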