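#' @import methods
#' @importFrom stats pchisq phyper pnorm qnorm dnorm pt qt var sd cor
#'   rbinom rnorm runif p.adjust setNames complete.cases glm binomial
#'   coef vcov t.test cor.test quantile fisher.test plogis qlogis
#'   model.matrix
#' @importFrom utils read.table write.table head tail
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

#' GenotypeDataset: samples-by-variants SNP call container
#'
#' An S4 container for biallelic autosomal SNP genotypes of a
#' case-control cohort, extending
#' \linkS4class{RangedSummarizedExperiment}.  The single assay,
#' \code{"calls"}, is an integer matrix (variants in rows, samples in
#' columns) counting copies of allele B, so every non-missing call is
#' 0, 1 or 2; missing genotypes are \code{NA}.  The variant map is the
#' \code{rowRanges} (width-1 \code{GRanges} on chromosomes
#' \code{"1"}..\code{"22"}, 1-based positions, metadata columns
#' \code{alleleA}/\code{alleleB}), and the samples live in
#' \code{colData} with \code{sex} (\code{"male"}, \code{"female"} or
#' \code{"unknown"}) and \code{phenotype} (0 = control, 1 = case,
#' \code{NA} = missing).
#'
#' Validity requires calls in \{0, 1, 2, NA\}, chromosomes in 1..22,
#' positions >= 1 sorted within each chromosome, and unique sample
#' ids.
#'
#' @seealso \code{\link{GenotypeDataset}} (constructor),
#'   \code{\link{genotypeCalls}}, \code{\link{variantInfo}},
#'   \code{\link{sampleInfo}}, \code{\link{readPlink}}
#' @name GenotypeDataset-class
#' @exportClass GenotypeDataset
setClass("GenotypeDataset", contains = "RangedSummarizedExperiment")

.validGenotypeDataset <- function(object) {
    msg <- character()
    if (!"calls" %in% SummarizedExperiment::assayNames(object))
        return("assay 'calls' is required")
    calls <- SummarizedExperiment::assay(object, "calls")
    bad <- calls[!is.na(calls)]
    if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
        msg <- c(msg, "non-missing calls must be 0, 1 or 2")
    chrom <- as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(object)))
    if (length(chrom) && !all(chrom %in% as.character(1:22)))
        msg <- c(msg, "chromosomes must be autosomes 1-22")
    pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(object))
    if (length(pos) && any(pos < 1L))
        msg <- c(msg, "positions must be >= 1")
    if (length(pos) > 1L) {
        o <- order(match(chrom, unique(chrom)), pos)
        if (!identical(o, seq_along(pos)))
            msg <- c(msg, "variants must be sorted by position within chromosome")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("sex", "phenotype") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'sex' and 'phenotype'")
    if (anyDuplicated(rownames(cd)))
        msg <- c(msg, "sample ids must be unique")
    ph <- cd$phenotype
    if (length(ph) && !all(ph[!is.na(ph)] %in% c(0L, 1L)))
        msg <- c(msg, "phenotype must be 0 (control), 1 (case) or NA")
    if (length(msg)) msg else TRUE
}
setValidity("GenotypeDataset", .validGenotypeDataset)

#' Construct a GenotypeDataset
#'
#' @param calls integer matrix of allele-B dosages, variants in rows and
#'   samples in columns (0/1/2/\code{NA}).
#' @param variants data.frame with columns \code{id}, \code{chrom}
#'   (integer 1-22), \code{bp} (1-based position), \code{alleleA},
#'   \code{alleleB}; one row per row of \code{calls}, sorted by
#'   position within chromosome.
#' @param samples data.frame with columns \code{id}, \code{sex},
#'   \code{phenotype} (0/1/\code{NA}); one row per column of
#'   \code{calls}.  \code{sex} defaults to \code{"unknown"} and
#'   \code{phenotype} to \code{NA} when absent.
#' @return A \linkS4class{GenotypeDataset}.
#' @examples
#' calls <- matrix(c(0L, 1L, 2L, 2L, 1L, 0L), nrow = 3)
#' variants <- data.frame(id = paste0("rs", 1:3), chrom = 1,
#'                        bp = c(100, 200, 300),
#'                        alleleA = "A", alleleB = "G")
#' samples <- data.frame(id = c("s1", "s2"), phenotype = c(1, 0))
#' gd <- GenotypeDataset(calls, variants, samples)
#' @export
GenotypeDataset <- function(calls, variants, samples) {
    calls <- as.matrix(calls)
    storage.mode(calls) <- "integer"
    stopifnot(nrow(calls) == nrow(variants), ncol(calls) == nrow(samples))
    if (is.null(samples$sex)) samples$sex <- "unknown"
    if (is.null(samples$phenotype)) samples$phenotype <- NA_integer_
    chrom <- as.integer(variants$chrom)
    keep <- chrom >= 1L & chrom <= 22L
    if (!all(keep)) {
        warning(sum(!keep), " variant(s) on non-autosomal chromosomes dropped")
        variants <- variants[keep, , drop = FALSE]
        calls <- calls[keep, , drop = FALSE]
        chrom <- chrom[keep]
    }
    o <- order(chrom, variants$bp)
    variants <- variants[o, , drop = FALSE]
    calls <- calls[o, , drop = FALSE]
    rr <- GenomicRanges::GRanges(
        seqnames = as.character(as.integer(variants$chrom)),
        ranges = IRanges::IRanges(start = as.integer(variants$bp), width = 1L),
        alleleA = as.character(variants$alleleA),
        alleleB = as.character(variants$alleleB))
    names(rr) <- as.character(variants$id)
    cd <- S4Vectors::DataFrame(
        sex = as.character(samples$sex),
        phenotype = as.integer(samples$phenotype),
        row.names = as.character(samples$id))
    dimnames(calls) <- list(names(rr), rownames(cd))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(calls = calls), rowRanges = rr, colData = cd)
    new("GenotypeDataset", se)
}

setMethod("show", "GenotypeDataset", function(object) {
    ph <- phenotypes(object)
    cat("GenotypeDataset:", nrow(object), "variants x", ncol(object),
        "samples\n")
    cat("  chromosomes:",
        paste(unique(as.character(GenomicRanges::seqnames(
            SummarizedExperiment::rowRanges(object)))), collapse = " "), "\n")
    cat("  cases:", sum(ph == 1L, na.rm = TRUE),
        " controls:", sum(ph == 0L, na.rm = TRUE),
        " missing phenotype:", sum(is.na(ph)), "\n")
})

#' Accessors for GenotypeDataset
#'
#' \code{genotypeCalls} returns the variants-by-samples integer dosage
#' matrix; \code{variantInfo} the variant map as a data.frame (id,
#' chrom, bp, alleleA, alleleB); \code{sampleInfo} the sample table
#' (id, sex, phenotype); \code{phenotypes} the named 0/1/\code{NA}
#' phenotype vector.
#'
#' @param x a \linkS4class{GenotypeDataset}.
#' @return See description.
#' @name genotype-accessors
#' @aliases genotypeCalls variantInfo sampleInfo phenotypes
#' @export genotypeCalls variantInfo sampleInfo phenotypes
NULL

genotypeCalls <- function(x) SummarizedExperiment::assay(x, "calls")

variantInfo <- function(x) {
    rr <- SummarizedExperiment::rowRanges(x)
    data.frame(id = names(rr),
               chrom = as.integer(as.character(GenomicRanges::seqnames(rr))),
               bp = GenomicRanges::start(rr),
               alleleA = S4Vectors::mcols(rr)$alleleA,
               alleleB = S4Vectors::mcols(rr)$alleleB,
               row.names = NULL, stringsAsFactors = FALSE)
}

sampleInfo <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    data.frame(id = rownames(cd), sex = cd$sex, phenotype = cd$phenotype,
               row.names = NULL, stringsAsFactors = FALSE)
}

phenotypes <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    setNames(cd$phenotype, rownames(cd))
}
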