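## SNP-based genomic inbreeding coefficients.  For genotype x (0/1/2
## copies of allele B), allele frequency p and q = 1 - p, the per-SNP
## terms are
##   F1: (x - 2p)^2 / (2pq) - 1   (variance of additive genotype)
##   F2: 1 - x(2 - x) / (2pq)     (excess homozygosity)
##   F3: (x^2 - (1 + 2p)x + 2p^2) / (2pq)
##                                (correlation of uniting gametes)
## each averaged over an individual's usable SNPs.  F3 equals the
## diagonal of the genetic relationship matrix minus one.

.freqB <- function(calls) {
    nm <- rowSums(!is.na(calls))
    ifelse(nm > 0L, rowSums(calls, na.rm = TRUE) / (2 * nm), NA_real_)
}

## per-individual means of the three per-SNP terms over rows `idx`
.fTerms <- function(calls, p, idx) {
    p <- p[idx]
    usable <- !is.na(p) & p > 0 & p < 1
    idx <- idx[usable]
    p <- p[usable]
    if (!length(idx))
        return(data.frame(f1 = NA_real_, f2 = NA_real_, f3 = NA_real_,
                          nSnp = 0L)[rep(1L, ncol(calls)), ])
    x <- calls[idx, , drop = FALSE]
    het2pq <- 2 * p * (1 - p)
    t1 <- (x - 2 * p)^2 / het2pq
    t2 <- 1 - x * (2 - x) / het2pq
    t3 <- (x^2 - (1 + 2 * p) * x + 2 * p^2) / het2pq
    nm <- colSums(!is.na(x))
    data.frame(f1 = colMeans(t1, na.rm = TRUE) - 1,
               f2 = colMeans(t2, na.rm = TRUE),
               f3 = colMeans(t3, na.rm = TRUE),
               nSnp = nm)
}

#' Genomic inbreeding coefficients per individual
#'
#' Computes the three SNP-based inbreeding estimators F1 (variance of
#' additive genotypes), F2 (excess homozygosity) and F3 (correlation
#' between uniting gametes) for every individual, averaging the
#' per-SNP terms over that individual's non-missing genotypes at
#' polymorphic SNPs.  Allele frequencies default to estimates from
#' the full sample (cases and controls combined); external reference
#' frequencies may be supplied instead.
#'
#' @param x a \linkS4class{GenotypeDataset}.
#' @param freq optional numeric vector of allele-B frequencies, one
#'   per variant, replacing the in-sample estimates.
#' @return data.frame with columns \code{sampleId}, \code{f1},
#'   \code{f2}, \code{f3}, \code{nSnp} (usable SNPs; individuals with
#'   none carry \code{NA} coefficients).
#' @export
inbreedingCoefficients <- function(x, freq = NULL) {
    calls <- genotypeCalls(x)
    p <- if (is.null(freq)) .freqB(calls) else freq
    stopifnot(length(p) == nrow(calls))
    res <- .fTerms(calls, p, seq_len(nrow(calls)))
    data.frame(sampleId = colnames(calls), res,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-chromosome inbreeding coefficients and case-control tests
#'
#' Restricts each estimator to one chromosome's SNPs, then tests
#' cases against controls per chromosome and estimator with a
#' two-sample Student's t-test.  The genome-wide coefficient equals
#' the SNP-count-weighted mean of the per-chromosome coefficients.
#'
#' @param x a \linkS4class{GenotypeDataset}.
#' @param freq optional allele-B frequencies as in
#'   \code{\link{inbreedingCoefficients}}.
#' @return list with \code{profiles} (long data.frame: sampleId,
#'   chrom, f1, f2, f3, nSnp) and \code{tests} (chrom, coefficient,
#'   meanCases, meanControls, statistic, p).
#' @export
perChromosomeF <- function(x, freq = NULL) {
    calls <- genotypeCalls(x)
    vi <- variantInfo(x)
    p <- if (is.null(freq)) .freqB(calls) else freq
    ph <- phenotypes(x)
    chroms <- unique(vi$chrom)
    profiles <- list(); tests <- list()
    for (ch in chroms) {
        idx <- which(vi$chrom == ch)
        if (length(idx) < 2L) {
            warning("chromosome ", ch, " has fewer than 2 SNPs; omitted")
            next
        }
        res <- .fTerms(calls, p, idx)
        profiles[[as.character(ch)]] <- data.frame(
            sampleId = colnames(calls), chrom = ch, res,
            row.names = NULL, stringsAsFactors = FALSE)
        for (coefName in c("f1", "f2", "f3")) {
            v <- res[[coefName]]
            xs <- v[!is.na(ph) & ph == 1L]
            ys <- v[!is.na(ph) & ph == 0L]
            if (sum(!is.na(xs)) < 2L || sum(!is.na(ys)) < 2L) next
            tt <- twoSampleT(xs[!is.na(xs)], ys[!is.na(ys)])
            tests[[paste(ch, coefName)]] <- data.frame(
                chrom = ch, coefficient = coefName,
                meanCases = mean(xs, na.rm = TRUE),
                meanControls = mean(ys, na.rm = TRUE),
                statistic = tt$statistic, p = tt$p,
                stringsAsFactors = FALSE)
        }
    }
    list(profiles = do.call(rbind, c(profiles, list(make.row.names = FALSE))),
         tests = do.call(rbind, c(tests, list(make.row.names = FALSE))))
}

#' Logistic regression of disease status on an inbreeding coefficient
#'
#' Fits \code{status ~ F + covariates} by maximum-likelihood logistic
#' regression and reports the coefficient, standard error and Wald
#' p-value of the inbreeding term.  Typical covariates are sex, the
#' leading ancestry principal components and per-sample missingness.
#'
#' @param f numeric inbreeding coefficient per individual.
#' @param phenotype binary 0/1 response (NA rows dropped).
#' @param covariates optional data.frame or matrix of additional
#'   covariates.
#' @return list with \code{coefficients} (full glm coefficient table
#'   as a data.frame with term, estimate, se, z, p), \code{fTerm} (the
#'   inbreeding row), \code{separation} flag, and the fitted
#'   \code{model}.
#' @export
inbreedingGLM <- function(f, phenotype, covariates = NULL) {
    df <- data.frame(status = phenotype, f = f)
    if (!is.null(covariates)) {
        covariates <- as.data.frame(covariates)
        df <- cbind(df, covariates)
    }
    df <- df[complete.cases(df), , drop = FALSE]
    if (var(df$f) == 0) stop("inbreeding coefficient is constant (rank deficient)")
    qrX <- qr(model.matrix(status ~ ., data = df))
    if (qrX$rank < ncol(qrX$qr)) stop("covariate matrix is rank deficient")
    fit <- suppressWarnings(glm(status ~ ., data = df, family = binomial()))
    separation <- !fit$converged || any(abs(coef(fit)) > 50 &
                                        sqrt(diag(vcov(fit))) > 50)
    ct <- summary(fit)$coefficients
    tab <- data.frame(term = rownames(ct), estimate = ct[, 1],
                      se = ct[, 2], z = ct[, 3], p = ct[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
    list(coefficients = tab,
         fTerm = tab[tab$term == "f", , drop = FALSE],
         separation = separation,
         model = fit)
}
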