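## Genome-wide SNP-by-SNP homozygosity association: at each SNP the
## 2x2 table of (case/control) x (homozygous/heterozygous) carriers is
## tested with the uncorrected chi-square, a one-sided Fisher exact
## test in the direction of excess homozygosity in cases, and BH FDR
## control across the scan.

#' Homozygosity association from per-SNP count quadruples
#'
#' Core of \code{\link{snpHomozygosityScan}}, exposed so that
#' published per-SNP homozygote/heterozygote counts can be re-tested
#' directly.  Rows with a zero marginal are flagged untestable and
#' excluded from the FDR ranking (their q is \code{NA}).
#'
#' @param counts data.frame with integer columns \code{casesHom},
#'   \code{casesHet}, \code{controlsHom}, \code{controlsHet}.
#' @param mTotal total number of tests for the FDR adjustment
#'   (default: number of testable rows).
#' @return \code{counts} with appended \code{chi2}, \code{p}, \code{q},
#'   \code{pFisher}, \code{orFisher}, \code{orCiLow}, \code{orCiHigh},
#'   \code{testable}.
#' @examples
#' homozygosityAssocFromCounts(
#'     data.frame(casesHom = 519, casesHet = 116,
#'                controlsHom = 274, controlsHet = 157),
#'     mTotal = 536270)
#' @export
homozygosityAssocFromCounts <- function(counts, mTotal = NULL) {
    a <- as.numeric(counts$casesHom);    b <- as.numeric(counts$casesHet)
    cc <- as.numeric(counts$controlsHom); d <- as.numeric(counts$controlsHet)
    n <- a + b + cc + d
    r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
    testable <- r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0
    chi2 <- ifelse(testable, n * (a * d - b * cc)^2 / (r1 * r2 * c1 * c2),
                   NA_real_)
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
    ## one-sided Fisher, H1: cases more often homozygous
    pFisher <- ifelse(testable,
                      phyper(a - 1, r1, r2, c1, lower.tail = FALSE),
                      NA_real_)
    zeroCell <- a == 0 | b == 0 | cc == 0 | d == 0
    aa <- a + 0.5 * zeroCell; bb <- b + 0.5 * zeroCell
    cca <- cc + 0.5 * zeroCell; dd <- d + 0.5 * zeroCell
    orF <- (a * d) / (b * cc)
    se <- sqrt(1 / aa + 1 / bb + 1 / cca + 1 / dd)
    orC <- (aa * dd) / (bb * cca)
    if (is.null(mTotal)) mTotal <- sum(testable)
    q <- rep(NA_real_, length(p))
    q[testable] <- bhFdr(p[testable], mTotal = mTotal)
    out <- counts
    out$chi2 <- chi2
    out$p <- p
    out$q <- q
    out$pFisher <- pFisher
    out$orFisher <- orF
    out$orCiLow <- exp(log(orC) - 1.959963984540054 * se)
    out$orCiHigh <- exp(log(orC) + 1.959963984540054 * se)
    out$testable <- testable
    out
}

#' Genome-wide SNP-by-SNP homozygosity scan
#'
#' For every variant, counts homozygous (both homozygote classes
#' pooled) and heterozygous carriers among cases and controls
#' (missing calls reduce that SNP's table only; samples with missing
#' phenotype are excluded throughout), then applies
#' \code{\link{homozygosityAssocFromCounts}}.
#'
#' @param x a \linkS4class{GenotypeDataset} with at least one case and
#'   one control.
#' @param mTotal total test count for the FDR adjustment (default:
#'   number of testable SNPs in the scan).
#' @return data.frame with one row per variant: \code{id},
#'   \code{chrom}, \code{bp}, the four counts, \code{chi2}, \code{p},
#'   \code{q}, \code{pFisher}, \code{orFisher}, CI bounds and
#'   \code{testable}.
#' @export
snpHomozygosityScan <- function(x, mTotal = NULL) {
    ph <- phenotypes(x)
    caseIdx <- which(!is.na(ph) & ph == 1L)
    ctrlIdx <- which(!is.na(ph) & ph == 0L)
    if (!length(caseIdx) || !length(ctrlIdx))
        stop("scan requires at least one case and one control")
    calls <- genotypeCalls(x)
    gCase <- calls[, caseIdx, drop = FALSE]
    gCtrl <- calls[, ctrlIdx, drop = FALSE]
    casesHet <- rowSums(gCase == 1L, na.rm = TRUE)
    casesHom <- rowSums(!is.na(gCase)) - casesHet
    controlsHet <- rowSums(gCtrl == 1L, na.rm = TRUE)
    controlsHom <- rowSums(!is.na(gCtrl)) - controlsHet
    vi <- variantInfo(x)
    counts <- data.frame(id = vi$id, chrom = vi$chrom, bp = vi$bp,
                         casesHom = casesHom, casesHet = casesHet,
                         controlsHom = controlsHom,
                         controlsHet = controlsHet,
                         row.names = NULL, stringsAsFactors = FALSE)
    homozygosityAssocFromCounts(counts, mTotal = mTotal)
}
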