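## Per-individual ROH burden, F_ROH, case-control burden tests and
## categorical odds-ratio tables.

#' Total SNP-mappable autosomal genome length (bp)
#'
#' Default denominator of F_ROH: the length of the autosomal genome
#' captured by the marker map, excluding centromeres
#' (2,677,608,286 bp).
#' @export
L_AUTO_BP <- 2677608286

#' Per-individual ROH burden summaries
#'
#' Counts, total and mean length of ROH segments of at least
#' \code{minKb} per individual, plus the genomic inbreeding measure
#' \eqn{F_{ROH} = \sum L_{ROH} / L_{AUTO}} and its split into short
#' (< \code{splitKb}) and long (>= \code{splitKb}) segment classes.
#' Samples with no qualifying segment are included with zeros.
#'
#' @param segments ROH \code{GRanges} as returned by
#'   \code{\link{scanRoh}}.
#' @param sampleIds character vector of all cohort sample ids (so
#'   ROH-free individuals appear); defaults to the ids present in
#'   \code{segments}.
#' @param minKb length criterion for inclusion, in kb (1000).
#' @param splitKb boundary between the short and long F_ROH classes
#'   (1500).
#' @param lAutoBp F_ROH denominator in bp.
#' @return data.frame with columns \code{sampleId}, \code{nRoh},
#'   \code{totalKb}, \code{meanKb}, \code{fRoh}, \code{fRohShort},
#'   \code{fRohLong}.
#' @export
individualBurden <- function(segments, sampleIds = NULL, minKb = 1000,
                             splitKb = 1500, lAutoBp = L_AUTO_BP) {
    stopifnot(minKb >= 0, lAutoBp > 0)
    sid <- S4Vectors::mcols(segments)$sampleId
    lenKb <- S4Vectors::mcols(segments)$lengthKb
    lenBp <- GenomicRanges::width(segments)
    keep <- lenKb >= minKb
    sid <- sid[keep]; lenKb <- lenKb[keep]; lenBp <- lenBp[keep]
    if (is.null(sampleIds)) sampleIds <- sort(unique(sid))
    f <- factor(sid, levels = sampleIds)
    nRoh <- as.integer(table(f))
    totalKb <- as.numeric(tapply(lenKb, f, sum, default = 0))
    totalBp <- as.numeric(tapply(lenBp, f, sum, default = 0))
    shortBp <- as.numeric(tapply(lenBp * (lenKb < splitKb), f, sum,
                                 default = 0))
    data.frame(sampleId = sampleIds,
               nRoh = nRoh,
               totalKb = totalKb,
               meanKb = ifelse(nRoh > 0L, totalKb / nRoh, 0),
               fRoh = totalBp / lAutoBp,
               fRohShort = shortBp / lAutoBp,
               fRohLong = (totalBp - shortBp) / lAutoBp,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Case-control t-tests on ROH burden metrics
#'
#' Two-sample Student's t-tests (pooled variance) comparing cases
#' against controls for the number of segments, the total segment
#' length and the mean segment length per individual, and for F_ROH.
#'
#' @param burden data.frame from \code{\link{individualBurden}}.
#' @param phenotype named or positional 0/1 vector aligned with
#'   \code{burden} rows (\code{NA} dropped).
#' @param alternative passed to \code{\link{twoSampleT}} with cases as
#'   the first sample (default two-sided).
#' @return data.frame with one row per metric: \code{metric},
#'   \code{meanCases}, \code{meanControls}, \code{statistic}, \code{p}.
#' @export
burdenTTests <- function(burden, phenotype,
                         alternative = "two.sided") {
    stopifnot(nrow(burden) == length(phenotype))
    metrics <- c(nRoh = "nRoh", totalKb = "totalKb", meanKb = "meanKb",
                 fRoh = "fRoh")
    isCase <- !is.na(phenotype) & phenotype == 1L
    isCtrl <- !is.na(phenotype) & phenotype == 0L
    if (sum(isCase) < 2L || sum(isCtrl) < 2L)
        stop("each phenotype stratum needs at least 2 individuals")
    rows <- lapply(names(metrics), function(m) {
        xs <- burden[[m]][isCase]
        ys <- burden[[m]][isCtrl]
        tt <- twoSampleT(xs, ys, alternative = alternative)
        data.frame(metric = m, meanCases = mean(xs), meanControls = mean(ys),
                   statistic = tt$statistic, p = tt$p,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Categorical odds-ratio table for a burden metric
#'
#' Bins a burden metric into ordered categories (empirical quartiles
#' of the pooled case+control distribution by default, chosen to give
#' approximately equal group sizes) and reports, for each category
#' above the lowest, the Woolf odds ratio against the reference
#' category with its 95\% CI and the uncorrected chi-square p-value.
#' Intervals are right-closed; ties fall in the lower category.
#'
#' @param burden data.frame from \code{\link{individualBurden}}.
#' @param phenotype 0/1 vector aligned with \code{burden} rows.
#' @param metric one of \code{"nRoh"}, \code{"totalMb"} (total length
#'   in Mb), \code{"totalKb"}, \code{"meanKb"}, \code{"fRoh"}.
#' @param cutoffs strictly increasing inner cut points, or
#'   \code{"quartiles"}.
#' @return data.frame with one row per category: \code{category},
#'   \code{cases}, \code{controls}, \code{or}, \code{ciLow},
#'   \code{ciHigh}, \code{p}, \code{empty}; the first row is the
#'   reference.
#' @export
burdenCategoryOR <- function(burden, phenotype, metric = "nRoh",
                             cutoffs = "quartiles") {
    stopifnot(nrow(burden) == length(phenotype))
    vals <- switch(metric,
                   nRoh = burden$nRoh,
                   totalMb = burden$totalKb / 1000,
                   totalKb = burden$totalKb,
                   meanKb = burden$meanKb,
                   fRoh = burden$fRoh,
                   stop("unknown metric: ", metric))
    keep <- !is.na(phenotype)
    vals <- vals[keep]; ph <- phenotype[keep]
    if (identical(cutoffs, "quartiles"))
        cutoffs <- unique(quantile(vals, c(0.25, 0.5, 0.75), names = FALSE))
    if (is.unsorted(cutoffs, strictly = TRUE))
        stop("cutoffs must be strictly increasing")
    cat <- cut(vals, breaks = c(-Inf, cutoffs, Inf), right = TRUE)
    counts <- table(factor(ph, levels = c(1L, 0L)), cat)
    refCases <- counts[1L, 1L]; refCtrls <- counts[2L, 1L]
    rows <- lapply(seq_len(ncol(counts)), function(j) {
        aj <- counts[1L, j]; cj <- counts[2L, j]
        if (j == 1L)
            return(data.frame(category = colnames(counts)[j],
                              cases = aj, controls = cj, or = 1,
                              ciLow = NA_real_, ciHigh = NA_real_,
                              p = NA_real_, empty = aj + cj == 0L,
                              stringsAsFactors = FALSE))
        empty <- aj + cj == 0L
        if (empty || refCases + refCtrls == 0L)
            return(data.frame(category = colnames(counts)[j],
                              cases = aj, controls = cj, or = NA_real_,
                              ciLow = NA_real_, ciHigh = NA_real_,
                              p = NA_real_, empty = TRUE,
                              stringsAsFactors = FALSE))
        tab <- c(aj, refCases, cj, refCtrls)
        orw <- oddsRatioWoolf(tab)
        pv <- tryCatch(chisq2x2(tab)$p, error = function(e) NA_real_)
        data.frame(category = colnames(counts)[j],
                   cases = aj, controls = cj, or = orw$estimate,
                   ciLow = orw$ciLow, ciHigh = orw$ciHigh, p = pv,
                   empty = FALSE, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
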