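## Sliding-window ROH caller in the PLINK 1 style, plus the
## random-ROH length threshold and the LD tag-group count used to
## inflate it.

#' ROH caller parameters
#'
#' Parameter bundle for \code{\link{scanRoh}}.  Defaults follow PLINK
#' 1.07's documented homozygosity-scan defaults with one override:
#' \code{windowHet = 0}, i.e. no heterozygous call is permitted in any
#' scanning window, which prevents overestimating the number and size
#' of ROHs.  \code{minSnp} defaults to 75 consecutive homozygous
#' calls, an LD-adjusted inflation of the ~53 calls needed to keep the
#' expected number of chance runs below 5\% genome-wide (see
#' \code{\link{minRohSnps}} and \code{\link{effectiveRohSnps}}).
#'
#' @param windowSnp scanning window size in SNPs (50).
#' @param windowHet maximum heterozygous calls per homozygous window
#'   (0).
#' @param windowMissing maximum missing calls per homozygous window
#'   (5).
#' @param windowThreshold minimum fraction of overlapping windows that
#'   must be fully homozygous for a SNP to be ROH-eligible (0.05).
#' @param minSnp minimum SNPs per emitted segment (75).
#' @param minKb minimum segment length in kb (1000).
#' @param minDensityKbPerSnp maximum average kb per SNP within a
#'   segment (50).
#' @param maxGapKb maximum gap between consecutive SNPs within a
#'   segment, in kb (1000).
#' @return A named list of class \code{rohParams}.
#' @export
rohParams <- function(windowSnp = 50L, windowHet = 0L, windowMissing = 5L,
                      windowThreshold = 0.05, minSnp = 75L, minKb = 1000,
                      minDensityKbPerSnp = 50, maxGapKb = 1000) {
    p <- list(windowSnp = as.integer(windowSnp),
              windowHet = as.integer(windowHet),
              windowMissing = as.integer(windowMissing),
              windowThreshold = windowThreshold,
              minSnp = as.integer(minSnp), minKb = minKb,
              minDensityKbPerSnp = minDensityKbPerSnp,
              maxGapKb = maxGapKb)
    if (any(vapply(p, function(v) v < 0, logical(1))))
        stop("all ROH parameters must be non-negative")
    if (p$windowSnp < 1L || p$minSnp < 1L)
        stop("windowSnp and minSnp must be >= 1")
    class(p) <- "rohParams"
    p
}

#' Minimum run length producing fewer than alpha chance ROHs
#'
#' Smallest integer L such that
#' \eqn{(1 - h)^L \cdot m \cdot n \le \alpha}, where h is the mean
#' per-SNP heterozygosity, m the number of SNPs and n the number of
#' individuals: the expected number of length-L runs of homozygous
#' calls arising by chance across the whole study is then at most
#' alpha.
#'
#' @param meanHet mean heterozygosity, in (0, 1).
#' @param nSnps,nSamples marker and cohort counts (>= 1).
#' @param alpha tolerated expected number of chance runs, in (0, 1).
#' @return integer L.
#' @examples
#' minRohSnps(0.35, 536270, 1080)   # 54
#' minRohSnps(0.355, 536270, 1080)  # 53
#' @export
minRohSnps <- function(meanHet, nSnps, nSamples, alpha = 0.05) {
    if (meanHet <= 0 || meanHet >= 1) stop("meanHet must be in (0, 1)")
    if (nSnps < 1 || nSamples < 1) stop("nSnps and nSamples must be >= 1")
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
    L <- ceiling(log(alpha / (nSnps * nSamples)) / log(1 - meanHet))
    L <- max(1L, as.integer(L))
    ## guard against floating-point edge: enforce the inequality exactly
    while ((1 - meanHet)^L * nSnps * nSamples > alpha) L <- L + 1L
    while (L > 1L && (1 - meanHet)^(L - 1L) * nSnps * nSamples <= alpha)
        L <- L - 1L
    L
}

#' Inflate a run-length threshold for linkage disequilibrium
#'
#' SNP calls in LD are not independent, so a threshold derived for
#' independent calls is inflated to
#' \code{ceiling(L / (1 - reduction))}, where \code{reduction} is the
#' fractional loss of independent information, e.g.
#' \code{1 - countTagGroups(x)/nrow(x)}.  With the study-scale ~25\%
#' reduction, L = 53 inflates to ~71; the pinned pipeline default is
#' 75.
#'
#' @param minSnps threshold for independent calls.
#' @param reduction fraction in [0, 1).
#' @return integer inflated threshold.
#' @export
effectiveRohSnps <- function(minSnps, reduction) {
    if (reduction < 0 || reduction >= 1) stop("reduction must be in [0, 1)")
    as.integer(ceiling(minSnps / (1 - reduction)))
}

#' Count separable LD tag groups
#'
#' Greedy left-to-right tagging within each chromosome: a SNP joins
#' the current group when it lies within \code{windowKb} of the
#' group's seed SNP and its genotype-dosage r-squared with the seed
#' exceeds \code{r2Threshold}; otherwise it seeds a new group.
#'
#' @param x a \linkS4class{GenotypeDataset} (variants sorted by
#'   position).
#' @param r2Threshold squared dosage correlation threshold, in (0, 1].
#' @param windowKb maximum distance from the seed, in kb.
#' @return integer number of tag groups.
#' @export
countTagGroups <- function(x, r2Threshold = 0.8, windowKb = 250) {
    if (r2Threshold <= 0 || r2Threshold > 1)
        stop("r2Threshold must be in (0, 1]")
    calls <- genotypeCalls(x)
    vi <- variantInfo(x)
    total <- 0L
    for (ch in unique(vi$chrom)) {
        idx <- which(vi$chrom == ch)
        pos <- vi$bp[idx]
        g <- calls[idx, , drop = FALSE]
        seed <- 1L
        total <- total + 1L
        for (i in seq_along(idx)[-1]) {
            within <- (pos[i] - pos[seed]) <= windowKb * 1000
            r2 <- if (within) {
                r <- suppressWarnings(
                    cor(g[seed, ], g[i, ], use = "complete.obs"))
                if (is.na(r)) 0 else r^2
            } else 0
            if (!within || r2 <= r2Threshold) {
                seed <- i
                total <- total + 1L
            }
        }
    }
    total
}

## window eligibility for one individual-chromosome: fraction of
## overlapping windows that are "homozygous" must exceed the threshold
.rohEligible <- function(het, mis, p) {
    n <- length(het)
    W <- p$windowSnp
    if (n < W) return(rep(FALSE, n))
    nWin <- n - W + 1L
    hetCum <- cumsum(het)
    misCum <- cumsum(mis)
    winHet <- hetCum[W:n] - c(0L, hetCum)[1:nWin]
    winMis <- misCum[W:n] - c(0L, misCum)[1:nWin]
    winHom <- as.integer(winHet <= p$windowHet & winMis <= p$windowMissing)
    homCum <- c(0L, cumsum(winHom))
    i <- seq_len(n)
    lo <- pmax(1L, i - W + 1L)
    hi <- pmin(i, nWin)
    cnt <- homCum[hi + 1L] - homCum[lo]
    tot <- hi - lo + 1L
    cnt / tot > p$windowThreshold
}

## split a vector of SNP indices (one candidate run) at oversized gaps
.splitAtGaps <- function(idx, pos, maxGapBp) {
    if (length(idx) <= 1L) return(list(idx))
    gaps <- diff(pos[idx])
    cut <- which(gaps > maxGapBp)
    if (!length(cut)) return(list(idx))
    starts <- c(1L, cut + 1L)
    ends <- c(cut, length(idx))
    Map(function(s, e) idx[s:e], starts, ends)
}

#' Detect runs of homozygosity
#'
#' Sliding-window ROH detection per individual and chromosome.  A
#' window of \code{windowSnp} SNPs is "homozygous" when it contains at
#' most \code{windowHet} heterozygous and \code{windowMissing} missing
#' calls; each SNP is scored by the fraction of overlapping windows
#' that are homozygous and is ROH-eligible when that fraction exceeds
#' \code{windowThreshold}.  Maximal runs of consecutive eligible SNPs
#' are candidate segments; heterozygous calls terminate a run (missing
#' calls do not) and runs are split where the distance between
#' adjacent SNPs exceeds \code{maxGapKb}.  Candidates are emitted when
#' they hold at least \code{minSnp} SNPs, span at least \code{minKb}
#' kb and are no sparser than \code{minDensityKbPerSnp} kb per SNP.
#'
#' @param x a \linkS4class{GenotypeDataset}.
#' @param params a \code{\link{rohParams}} bundle.
#' @param samples optional character vector restricting the scan.
#' @return \code{GRanges} of segments (1-based inclusive bp intervals)
#'   with metadata columns \code{sampleId}, \code{nSnp},
#'   \code{lengthKb}.
#' @export
scanRoh <- function(x, params = rohParams(), samples = NULL) {
    stopifnot(is(x, "GenotypeDataset"), inherits(params, "rohParams"))
    calls <- genotypeCalls(x)
    vi <- variantInfo(x)
    if (!identical(order(match(vi$chrom, unique(vi$chrom)), vi$bp),
                   seq_len(nrow(vi))))
        stop("variants must be sorted by (chrom, bp)")
    sampleIds <- if (is.null(samples)) colnames(calls) else samples
    chromIdx <- split(seq_len(nrow(vi)), vi$chrom)
    out <- vector("list", length(sampleIds) * length(chromIdx))
    k <- 0L
    for (sid in sampleIds) {
        g <- calls[, sid]
        for (ch in names(chromIdx)) {
            idx <- chromIdx[[ch]]
            pos <- vi$bp[idx]
            gg <- g[idx]
            het <- !is.na(gg) & gg == 1L
            mis <- is.na(gg)
            elig <- .rohEligible(as.integer(het), as.integer(mis), params)
            elig <- elig & !het   # a heterozygous call never joins a run
            if (!any(elig)) next
            r <- rle(elig)
            ends <- cumsum(r$lengths)
            starts <- ends - r$lengths + 1L
            runs <- Map(function(s, e) s:e,
                        starts[r$values], ends[r$values])
            segs <- unlist(lapply(runs, .splitAtGaps, pos = pos,
                                  maxGapBp = params$maxGapKb * 1000),
                           recursive = FALSE)
            for (sg in segs) {
                nSnp <- length(sg)
                startBp <- pos[sg[1L]]
                endBp <- pos[sg[nSnp]]
                lengthKb <- (endBp - startBp + 1) / 1000
                if (nSnp < params$minSnp) next
                if (lengthKb < params$minKb) next
                if (lengthKb / nSnp > params$minDensityKbPerSnp) next
                k <- k + 1L
                out[[k]] <- data.frame(sampleId = sid,
                                       chrom = as.integer(ch),
                                       startBp = startBp, endBp = endBp,
                                       nSnp = nSnp, lengthKb = lengthKb)
            }
        }
    }
    rohSegments(if (k) do.call(rbind, out[seq_len(k)]) else NULL)
}

#' Build a ROH segment GRanges from a data.frame
#'
#' Standard representation of ROH segments used across the package: a
#' \code{GRanges} (1-based inclusive) with metadata columns
#' \code{sampleId}, \code{nSnp}, \code{lengthKb}.
#'
#' @param df data.frame with columns \code{sampleId}, \code{chrom},
#'   \code{startBp}, \code{endBp} and optionally \code{nSnp};
#'   \code{NULL} gives an empty segment set.
#' @return \code{GRanges}.
#' @export
rohSegments <- function(df = NULL) {
    if (is.null(df) || nrow(df) == 0L) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            sampleId = character(), nSnp = integer(), lengthKb = numeric())
        return(gr)
    }
    if (is.null(df$nSnp)) df$nSnp <- NA_integer_
    gr <- GenomicRanges::GRanges(
        seqnames = as.character(as.integer(df$chrom)),
        ranges = IRanges::IRanges(start = df$startBp, end = df$endBp),
        sampleId = as.character(df$sampleId),
        nSnp = as.integer(df$nSnp),
        lengthKb = (df$endBp - df$startBp + 1) / 1000)
    gr
}
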