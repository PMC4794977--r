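## Pooling of overlapping ROH segments across individuals, consensus
## (minimal shared) regions, recurrent-region filtering, and the
## case-control tests applied to recurrent regions.

#' Pool overlapping ROH segments
#'
#' Assigns every segment to a pool: pools are the connected components
#' of the interval-overlap graph within each chromosome (single
#' linkage, i.e. transitive closure of pairwise overlap, which on a
#' line is exactly the merge of overlapping intervals).  Bookended
#' segments that share no base pair are not pooled.
#'
#' @param segments ROH \code{GRanges} (see \code{\link{rohSegments}}).
#' @return \code{segments} with an added integer metadata column
#'   \code{poolId} (1-based, ordered by chromosome then pool start).
#' @export
poolOverlapping <- function(segments) {
    if (!length(segments)) {
        S4Vectors::mcols(segments)$poolId <- integer()
        return(segments)
    }
    comp <- GenomicRanges::reduce(segments, min.gapwidth = 0L,
                                  ignore.strand = TRUE)
    comp <- GenomicRanges::sort(comp)
    hits <- GenomicRanges::findOverlaps(segments, comp,
                                        ignore.strand = TRUE)
    poolId <- integer(length(segments))
    poolId[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
    S4Vectors::mcols(segments)$poolId <- poolId
    segments
}

#' Consensus regions of segment pools
#'
#' For each pool, the consensus region is the minimal interval shared
#' by all members: start = max of member starts, end = min of member
#' ends.  Because pooling is transitive, a pool's strict intersection
#' can be empty; such pools are flagged (\code{nonEmpty = FALSE}) and
#' carry \code{NA} consensus coordinates.  When the originating
#' dataset is supplied, the number of map SNPs inside the consensus
#' interval and the case/control carrier counts are added.
#'
#' @param segments pooled \code{GRanges} from
#'   \code{\link{poolOverlapping}}.
#' @param x optional \linkS4class{GenotypeDataset} providing the
#'   variant map and phenotypes.
#' @return data.frame with one row per pool: \code{poolId},
#'   \code{chrom}, \code{consensusStart}, \code{consensusEnd},
#'   \code{consensusKb}, \code{nSegments}, \code{nSamples},
#'   \code{nonEmpty}, and with \code{x}: \code{nSnp}, \code{nCases},
#'   \code{nControls}.
#' @export
consensusRegions <- function(segments, x = NULL) {
    pid <- S4Vectors::mcols(segments)$poolId
    if (is.null(pid)) stop("segments must carry poolId; run poolOverlapping")
    sid <- S4Vectors::mcols(segments)$sampleId
    chrom <- as.integer(as.character(GenomicRanges::seqnames(segments)))
    st <- GenomicRanges::start(segments)
    en <- GenomicRanges::end(segments)
    ids <- sort(unique(pid))
    f <- factor(pid, levels = ids)
    cStart <- as.numeric(tapply(st, f, max))
    cEnd <- as.numeric(tapply(en, f, min))
    nonEmpty <- cStart <= cEnd
    out <- data.frame(
        poolId = ids,
        chrom = as.integer(tapply(chrom, f, function(v) v[1L])),
        consensusStart = ifelse(nonEmpty, cStart, NA_real_),
        consensusEnd = ifelse(nonEmpty, cEnd, NA_real_),
        consensusKb = ifelse(nonEmpty, (cEnd - cStart + 1) / 1000, NA_real_),
        nSegments = as.integer(table(f)),
        nSamples = as.integer(tapply(sid, f,
                                     function(v) length(unique(v)))),
        nonEmpty = nonEmpty,
        row.names = NULL, stringsAsFactors = FALSE)
    if (!is.null(x)) {
        vi <- variantInfo(x)
        ph <- phenotypes(x)
        out$nSnp <- vapply(seq_len(nrow(out)), function(i) {
            if (!out$nonEmpty[i]) return(NA_integer_)
            sum(vi$chrom == out$chrom[i] &
                vi$bp >= out$consensusStart[i] &
                vi$bp <= out$consensusEnd[i])
        }, integer(1))
        carriers <- tapply(sid, f, unique)
        out$nCases <- vapply(carriers, function(v)
            sum(ph[v] == 1L, na.rm = TRUE), integer(1))
        out$nControls <- vapply(carriers, function(v)
            sum(ph[v] == 0L, na.rm = TRUE), integer(1))
    }
    out
}

#' Filter pools to recurrent ROH regions
#'
#' Keeps pools carried by at least \code{minSamples} distinct
#' individuals ("more than five" in the default) whose non-empty
#' consensus region spans at least \code{minKb}.
#'
#' @param pools data.frame from \code{\link{consensusRegions}}.
#' @param minSamples minimum distinct carriers (default 6).
#' @param minKb minimum consensus length in kb (default 500).
#' @return the qualifying rows of \code{pools}.
#' @export
filterRecurrent <- function(pools, minSamples = 6L, minKb = 500) {
    pools[pools$nonEmpty &
          pools$nSamples >= minSamples &
          !is.na(pools$consensusKb) & pools$consensusKb >= minKb, ,
          drop = FALSE]
}

#' Group identically-located ROH segments
#'
#' Groups segments sharing exactly equal (chromosome, start, end) with
#' at least \code{minSnp} SNPs — the strict "common ROH" definition of
#' identical start and end locations across individuals.
#'
#' @param segments ROH \code{GRanges}.
#' @param minSnp minimum member SNP count (default 75).
#' @return data.frame with one row per group: \code{chrom},
#'   \code{startBp}, \code{endBp}, \code{nSnp}, \code{size} (number of
#'   distinct carriers), sorted by decreasing size.
#' @export
commonRohGroups <- function(segments, minSnp = 75L) {
    nsnp <- S4Vectors::mcols(segments)$nSnp
    keep <- !is.na(nsnp) & nsnp >= minSnp
    segments <- segments[keep]
    if (!length(segments))
        return(data.frame(chrom = integer(), startBp = numeric(),
                          endBp = numeric(), nSnp = integer(),
                          size = integer()))
    key <- paste(GenomicRanges::seqnames(segments),
                 GenomicRanges::start(segments),
                 GenomicRanges::end(segments), sep = ":")
    sid <- S4Vectors::mcols(segments)$sampleId
    sizes <- tapply(sid, key, function(v) length(unique(v)))
    first <- !duplicated(key)
    out <- data.frame(
        chrom = as.integer(as.character(
            GenomicRanges::seqnames(segments)))[first],
        startBp = GenomicRanges::start(segments)[first],
        endBp = GenomicRanges::end(segments)[first],
        nSnp = S4Vectors::mcols(segments)$nSnp[first],
        size = as.integer(sizes[key[first]]),
        row.names = NULL, stringsAsFactors = FALSE)
    out[order(-out$size, out$chrom, out$startBp), , drop = FALSE]
}

#' Carrier-status association of pooled regions
#'
#' Uncorrected 2x2 chi-square of carrier status against case status
#' for each pool: carriers split case/control against the non-carrier
#' remainder of the cohort.
#'
#' @param pools data.frame with \code{nCases}, \code{nControls}
#'   columns (from \code{\link{consensusRegions}} with a dataset, or
#'   assembled from published carrier counts).
#' @param nCasesTotal,nControlsTotal cohort stratum sizes.
#' @return \code{pools} with appended \code{chi2}, \code{p},
#'   \code{testable}.
#' @examples
#' carrierAssociation(data.frame(nCases = 6, nControls = 15), 649, 431)
#' @export
carrierAssociation <- function(pools, nCasesTotal, nControlsTotal) {
    a <- as.numeric(pools$nCases)
    cc <- as.numeric(pools$nControls)
    if (any(a > nCasesTotal) || any(cc > nControlsTotal))
        stop("carrier counts exceed stratum totals")
    b <- nCasesTotal - a; d <- nControlsTotal - cc
    n <- a + b + cc + d
    c1 <- a + cc; c2 <- b + d
    testable <- c1 > 0 & c2 > 0
    chi2 <- ifelse(testable,
                   n * (a * d - b * cc)^2 /
                       ((a + b) * (cc + d) * c1 * c2),
                   NA_real_)
    pools$chi2 <- chi2
    pools$p <- pchisq(chi2, df = 1, lower.tail = FALSE)
    pools$testable <- testable
    pools
}

#' One-tailed test of per-SNP homozygote proportions in a region
#'
#' For every map SNP inside the given consensus region, the proportion
#' of homozygous genotypes is computed separately among cases and
#' controls; the two per-SNP proportion vectors are compared with an
#' unpaired one-tailed Student's t-test with H1: cases more homozygous
#' than controls.
#'
#' @param x a \linkS4class{GenotypeDataset}.
#' @param chrom,startBp,endBp region (1-based inclusive) holding at
#'   least 2 map SNPs.
#' @return data.frame as \code{\link{twoSampleT}} plus \code{nSnp}.
#' @export
homozygosityProportionTest <- function(x, chrom, startBp, endBp) {
    vi <- variantInfo(x)
    idx <- which(vi$chrom == chrom & vi$bp >= startBp & vi$bp <= endBp)
    if (length(idx) < 2L)
        stop("consensus region must contain at least 2 SNPs")
    ph <- phenotypes(x)
    calls <- genotypeCalls(x)[idx, , drop = FALSE]
    propHom <- function(g) {
        nm <- rowSums(!is.na(g))
        het <- rowSums(g == 1L, na.rm = TRUE)
        ifelse(nm > 0L, (nm - het) / nm, NA_real_)
    }
    pc <- propHom(calls[, !is.na(ph) & ph == 1L, drop = FALSE])
    pk <- propHom(calls[, !is.na(ph) & ph == 0L, drop = FALSE])
    ok <- !is.na(pc) & !is.na(pk)
    res <- twoSampleT(pc[ok], pk[ok], alternative = "greater")
    res$nSnp <- sum(ok)
    res
}
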