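## PLINK 1 binary I/O and basic per-variant / per-sample summaries.
## The .bed codec is written here because it is a fixed 2-bit format:
## magic 0x6c 0x1b, mode byte 0x01 (SNP-major), then ceiling(n/4) bytes
## per variant, two bits per sample in file order within each byte:
## 00 = hom A1, 01 = missing, 10 = het, 11 = hom A2.  With the .bim A1
## column holding allele A and A2 holding allele B, the 2-bit codes map
## to allele-B dosages 0, NA, 1, 2.

.BED_MAGIC <- as.raw(c(0x6c, 0x1b))

## 256 x 4 lookup: byte value -> four dosages (NA for missing)
.bedDecodeTable <- local({
    codes <- c(0L, NA_integer_, 1L, 2L)
    m <- matrix(NA_integer_, nrow = 256L, ncol = 4L)
    for (b in 0:255) {
        v <- b
        for (k in 1:4) {
            m[b + 1L, k] <- codes[(v %% 4L) + 1L]
            v <- v %/% 4L
        }
    }
    m
})

#' Read a PLINK binary fileset
#'
#' Reads a \code{.bed}/\code{.bim}/\code{.fam} triple into a
#' \linkS4class{GenotypeDataset}.  Only the SNP-major v1.00 layout is
#' supported.  Variant order follows the \code{.bim}; allele A is the
#' \code{.bim} A1 column, and calls count copies of allele B (the A2
#' column).  Non-autosomal variants are dropped with a warning.
#'
#' @param prefix path prefix; \code{<prefix>.bed} etc. are read.
#'   Alternatively pass the three paths explicitly.
#' @param bed,bim,fam explicit file paths (override \code{prefix}).
#' @return A \linkS4class{GenotypeDataset}.
#' @export
readPlink <- function(prefix, bed = paste0(prefix, ".bed"),
                      bim = paste0(prefix, ".bim"),
                      fam = paste0(prefix, ".fam")) {
    for (f in c(bed, bim, fam))
        if (!file.exists(f)) stop("file not found: ", f)
    bimTab <- read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("chrom", "id", "cm", "bp", "a1", "a2"))
    famTab <- read.table(fam, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("fid", "iid", "pat", "mat", "sex",
                                       "pheno"))
    nVar <- nrow(bimTab)
    nSam <- nrow(famTab)
    bytesPerVar <- (nSam + 3L) %/% 4L
    expect <- 3L + as.numeric(nVar) * bytesPerVar
    got <- file.size(bed)
    raw <- readBin(bed, what = "raw", n = got)
    if (length(raw) < 3L || !identical(raw[1:2], .BED_MAGIC))
        stop("malformed .bed magic bytes in ", bed)
    if (raw[3L] != as.raw(1L))
        stop(bed, " is not in SNP-major mode")
    if (got != expect)
        stop("size mismatch in ", bed, ": expected ", expect,
             " bytes for ", nVar, " variants x ", nSam,
             " samples, found ", got)
    body <- as.integer(raw[-(1:3)])
    ## decode all bytes at once, then keep the first nSam calls per variant
    dos <- .bedDecodeTable[body + 1L, , drop = FALSE]
    dos <- matrix(t(dos), nrow = 4L * bytesPerVar, ncol = nVar)
    calls <- t(dos[seq_len(nSam), , drop = FALSE])  # variants x samples

    sex <- c("male", "female")[match(famTab$sex, c(1L, 2L))]
    sex[is.na(sex)] <- "unknown"
    pheno <- rep(NA_integer_, nSam)
    pheno[famTab$pheno == 1] <- 0L
    pheno[famTab$pheno == 2] <- 1L
    GenotypeDataset(calls,
                    variants = data.frame(id = bimTab$id, chrom = bimTab$chrom,
                                          bp = bimTab$bp, alleleA = bimTab$a1,
                                          alleleB = bimTab$a2,
                                          stringsAsFactors = FALSE),
                    samples = data.frame(id = famTab$iid, sex = sex,
                                         phenotype = pheno,
                                         stringsAsFactors = FALSE))
}

#' Write a PLINK binary fileset
#'
#' Writes a \linkS4class{GenotypeDataset} as SNP-major
#' \code{.bed}/\code{.bim}/\code{.fam}.  Sex encodes as 1/2/0 and
#' phenotype as 1 (control) / 2 (case) / -9 (missing).
#'
#' @param x a \linkS4class{GenotypeDataset} with at least one sample
#'   and one variant.
#' @param prefix output path prefix.
#' @return Invisibly, the three file paths written.
#' @export
writePlink <- function(x, prefix) {
    stopifnot(is(x, "GenotypeDataset"))
    if (ncol(x) == 0L || nrow(x) == 0L)
        stop("refusing to write an empty dataset")
    vi <- variantInfo(x)
    si <- sampleInfo(x)
    calls <- genotypeCalls(x)
    nSam <- ncol(calls)
    bytesPerVar <- (nSam + 3L) %/% 4L

    ## dosage -> 2-bit code: 0 -> 0, NA -> 1, 1 -> 2, 2 -> 3; pad slots 0
    code <- matrix(0L, nrow = 4L * bytesPerVar, ncol = nrow(calls))
    cc <- calls
    cc[is.na(cc)] <- -1L
    code[seq_len(nSam), ] <- c(1L, 0L, 2L, 3L)[t(cc) + 2L]
    packed <- code[c(TRUE, FALSE, FALSE, FALSE), , drop = FALSE] +
        4L * code[c(FALSE, TRUE, FALSE, FALSE), , drop = FALSE] +
        16L * code[c(FALSE, FALSE, TRUE, FALSE), , drop = FALSE] +
        64L * code[c(FALSE, FALSE, FALSE, TRUE), , drop = FALSE]
    bedPath <- paste0(prefix, ".bed")
    bimPath <- paste0(prefix, ".bim")
    famPath <- paste0(prefix, ".fam")
    con <- file(bedPath, "wb")
    on.exit(close(con))
    writeBin(c(.BED_MAGIC, as.raw(1L)), con)
    writeBin(as.raw(packed), con)

    write.table(data.frame(vi$chrom, vi$id, 0L, vi$bp, vi$alleleA, vi$alleleB),
                bimPath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    sexCode <- c(male = 1L, female = 2L, unknown = 0L)[si$sex]
    sexCode[is.na(sexCode)] <- 0L
    phenoCode <- ifelse(is.na(si$phenotype), -9L,
                        ifelse(si$phenotype == 1L, 2L, 1L))
    write.table(data.frame(si$id, si$id, 0L, 0L, sexCode, phenoCode),
                famPath, sep = " ", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(c(bed = bedPath, bim = bimPath, fam = famPath))
}

#' Per-variant genotype summaries
#'
#' Allele-B frequency, heterozygosity rate, missingness and
#' homozygote/heterozygote counts per variant.  Frequencies and rates
#' are computed over non-missing calls only; variants with no
#' non-missing call are flagged \code{undefined}.
#'
#' @param x a \linkS4class{GenotypeDataset}.
#' @return data.frame with columns \code{id}, \code{freqB},
#'   \code{hetRate}, \code{missingRate}, \code{homCount},
#'   \code{hetCount}, \code{undefined}.
#' @export
perVariantStats <- function(x) {
    calls <- genotypeCalls(x)
    nSam <- ncol(calls)
    nonMissing <- rowSums(!is.na(calls))
    het <- rowSums(calls == 1L, na.rm = TRUE)
    bAlleles <- rowSums(calls, na.rm = TRUE)
    freq <- ifelse(nonMissing > 0L, bAlleles / (2 * nonMissing), NA_real_)
    data.frame(id = rownames(calls),
               freqB = freq,
               hetRate = ifelse(nonMissing > 0L, het / nonMissing, NA_real_),
               missingRate = (nSam - nonMissing) / nSam,
               homCount = nonMissing - het,
               hetCount = het,
               undefined = nonMissing == 0L,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample genotype summaries
#'
#' Missingness (fraction of all variants) and heterozygosity rate
#' (fraction of non-missing calls) per sample.
#'
#' @param x a \linkS4class{GenotypeDataset} with at least one variant.
#' @return data.frame with columns \code{id}, \code{missingRate},
#'   \code{hetRate}.
#' @export
perSampleStats <- function(x) {
    if (nrow(x) == 0L) stop("dataset has no variants")
    calls <- genotypeCalls(x)
    nonMissing <- colSums(!is.na(calls))
    het <- colSums(calls == 1L, na.rm = TRUE)
    data.frame(id = colnames(calls),
               missingRate = (nrow(calls) - nonMissing) / nrow(calls),
               hetRate = ifelse(nonMissing > 0L, het / nonMissing, NA_real_),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Remove variants inside flanked regions
#'
#' Drops every variant whose position falls in
#' \code{[start - flankBp, end + flankBp]} on the matching chromosome,
#' e.g. to excise known GWAS hit regions (plus/minus 500 kb) before a
#' heritability fit.  Intervals are 1-based and inclusive at both
#' ends.  All samples are kept.
#'
#' @param x a \linkS4class{GenotypeDataset}.
#' @param regions data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive, \code{start <= end}).
#' @param flankBp non-negative flank added on both sides, in bp.
#' @return A \linkS4class{GenotypeDataset} with the remaining variants.
#' @export
excludeRegions <- function(x, regions, flankBp = 0) {
    if (flankBp < 0) stop("flankBp must be non-negative")
    if (is.null(regions) || nrow(regions) == 0L) return(x)
    stopifnot(all(c("chrom", "start", "end") %in% colnames(regions)))
    if (any(regions$start > regions$end))
        stop("regions must have start <= end")
    vi <- variantInfo(x)
    drop <- rep(FALSE, nrow(vi))
    for (i in seq_len(nrow(regions))) {
        drop <- drop | (vi$chrom == as.integer(regions$chrom[i]) &
                        vi$bp >= regions$start[i] - flankBp &
                        vi$bp <= regions$end[i] + flankBp)
    }
    x[!drop, ]
}
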