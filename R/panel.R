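#' Construct a GenotypePanel
#'
#' @param geno integer matrix of B-allele dosages, loci x samples; values in
#'   \{0, 1, 2, NA\}.
#' @param loci `GRanges` of width-1 SNP positions, with metadata columns
#'   `alleleA`, `alleleB` and optionally `chromClass` (defaults to
#'   `"autosome"`). Must be sorted within chromosome.
#' @param breed character vector of breed labels, one per sample.
#' @param sex optional per-sample sex, `"F"`/`"M"`/`NA`.
#' @param hapA,hapB optional phased 0/1 haplotype matrices with the same
#'   dimensions as `geno`; their sum must equal `geno` wherever called.
#' @param sampleIds sample identifiers; default taken from `colnames(geno)`.
#' @return a [GenotypePanel-class] object.
#' @examples
#' loci <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 200), width = 1),
#'     alleleA = "A", alleleB = "C", chromClass = "autosome")
#' geno <- matrix(c(0L, 2L, 1L, 1L), nrow = 2,
#'     dimnames = list(NULL, c("s1", "s2")))
#' GenotypePanel(geno, loci, breed = c("Beagle", "Boxer"))
#' @export
GenotypePanel <- function(geno, loci, breed, sex = NULL, hapA = NULL,
                          hapB = NULL, sampleIds = colnames(geno)) {
    geno <- as.matrix(geno)
    if (!is.integer(geno)) storage.mode(geno) <- "integer"
    if (is.null(sampleIds))
        sampleIds <- paste0("S", seq_len(ncol(geno)))
    if (is.null(sex))
        sex <- rep(NA_character_, ncol(geno))
    if (is.null(mcols(loci)$chromClass))
        mcols(loci)$chromClass <- "autosome"
    if (!identical(colnames(geno), sampleIds))
        colnames(geno) <- sampleIds
    assays <- list(geno = geno)
    if (!is.null(hapA) || !is.null(hapB)) {
        stopifnot(!is.null(hapA), !is.null(hapB))
        hapA <- as.matrix(hapA); hapB <- as.matrix(hapB)
        if (!is.integer(hapA)) storage.mode(hapA) <- "integer"
        if (!is.integer(hapB)) storage.mode(hapB) <- "integer"
        if (!identical(colnames(hapA), sampleIds))
            colnames(hapA) <- sampleIds
        if (!identical(colnames(hapB), sampleIds))
            colnames(hapB) <- sampleIds
        assays$hapA <- hapA
        assays$hapB <- hapB
    }
    cd <- DataFrame(breed = as.character(breed), sex = as.character(sex),
                    row.names = sampleIds)
    se <- SummarizedExperiment(assays = assays, rowRanges = loci, colData = cd)
    new("GenotypePanel", se)
}

#' @describeIn GenotypePanel breed label of every sample
#' @param x,object a GenotypePanel
#' @export
breeds <- function(x) as.character(colData(x)$breed)

#' @describeIn GenotypePanel unique breed names in panel order
#' @export
breedNames <- function(x) unique(breeds(x))

#' @describeIn GenotypePanel the dosage matrix (loci x samples)
#' @export
genotypes <- function(x) assay(x, "geno")

#' @describeIn GenotypePanel TRUE when phased haplotypes are present
#' @export
isPhased <- function(x) all(c("hapA", "hapB") %in% assayNames(x))

#' @describeIn GenotypePanel loci x (2 samples) haplotype matrix; columns are
#'   interleaved `<sample>.1`, `<sample>.2`
#' @export
haplotypes <- function(x) {
    stopifnot(isPhased(x))
    a <- assay(x, "hapA"); b <- assay(x, "hapB")
    h <- matrix(0L, nrow(a), 2L * ncol(a))
    h[, seq(1L, 2L * ncol(a), by = 2L)] <- a
    h[, seq(2L, 2L * ncol(a), by = 2L)] <- b
    colnames(h) <- paste(rep(colnames(a), each = 2L), 1:2, sep = ".")
    h
}

#' @describeIn GenotypePanel chromosome class of every locus
#' @export
chromClass <- function(x) as.character(mcols(rowRanges(x))$chromClass)

#' @describeIn GenotypePanel breed of each haplotype column (2 per sample)
#' @export
haplotypeBreeds <- function(x) rep(breeds(x), each = 2L)

setMethod("show", "GenotypePanel", function(object) {
    cat("GenotypePanel:", nrow(object), "loci x", ncol(object), "samples\n")
    cat("  breeds:", length(unique(breeds(object))),
        paste0("(", paste(head(breedNames(object), 6L), collapse = ", "),
               if (length(breedNames(object)) > 6L) ", ..." else "", ")"), "\n")
    cat("  phased:", isPhased(object), "\n")
    tab <- table(chromClass(object))
    cat("  chromClass:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
})

setMethod("show", "BreedFreq", function(object) {
    cat("BreedFreq:", nrow(object@freqB), "loci x", ncol(object@freqB),
        "breeds\n")
})

setMethod("show", "WindowStatTrack", function(object) {
    cat("WindowStatTrack[", object@statistic, "]: ",
        length(object@windows), " windows x ", ncol(object@values),
        " breeds\n", sep = "")
})

setMethod("show", "NullLengthDistribution", function(object) {
    for (st in names(object@lengths)) {
        n <- vapply(object@lengths[[st]], length, integer(1))
        cat("Null lengths [", st, "]: ", length(n), " breeds, ",
            sum(n), " regions\n", sep = "")
    }
})

setMethod("show", "DemographicModel", function(object) {
    cat("DemographicModel: Ne_wolf=", object@neWolf, " Ne_dog=", object@neDog,
        " T_dom=", object@tDom, " T_breed=", object@tBreed,
        " mu=", object@mu, " r=", object@recombRate, "\n", sep = "")
})

setMethod("show", "TraitTable", function(object) {
    cat("TraitTable '", object@trait, "' (", object@coding, "): ",
        length(object@values), " breeds\n", sep = "")
})

#' Construct a breed-level trait table
#'
#' @param values named numeric vector; names are breed labels. Breeds not
#'   listed are excluded from a GWAS using this trait.
#' @param coding `"quantitative"` or `"dichotomous"` (0/1 values).
#' @param trait trait name used in outputs.
#' @export
TraitTable <- function(values, coding = c("quantitative", "dichotomous"),
                       trait = "trait") {
    if (length(values) == 0L)
        stop("empty trait table")
    new("TraitTable", trait = trait, coding = match.arg(coding),
        values = values)
}

#' @describeIn TraitTable named phenotype values
#' @param x a TraitTable
#' @export
traitValues <- function(x) x@values

#' @describeIn TraitTable trait coding
#' @export
traitCoding <- function(x) x@coding
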