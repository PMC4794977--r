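## Elementary statistics used throughout the pipeline.  All 2x2 tests
## operate on cell counts (a, b) / (c, d) with rows = case/control and
## columns = exposure present/absent.  No Yates continuity correction
## is applied anywhere: the published per-SNP and carrier chi-square
## values are only reproduced by the plain Pearson statistic.

.as2x2 <- function(table) {
    m <- matrix(as.numeric(table), nrow = 2L, byrow = TRUE)
    if (any(m < 0) || sum(m) <= 0)
        stop("2x2 table needs non-negative cells and a positive total")
    m
}

#' Pearson chi-square test on a 2x2 table (no continuity correction)
#'
#' Computes \eqn{\chi^2 = n(ad-bc)^2/(r_1 r_2 c_1 c_2)} with 1 df.
#'
#' @param table cell counts \code{c(a, b, c, d)} in row-major order, or
#'   a 2x2 matrix.
#' @return data.frame with \code{statistic}, \code{df}, \code{p}.
#' @examples
#' chisq2x2(c(519, 116, 274, 157))  # statistic ~ 44.44
#' @export
chisq2x2 <- function(table) {
    m <- .as2x2(table)
    r <- rowSums(m); cl <- colSums(m)
    if (any(r == 0) || any(cl == 0))
        stop("chi-square undefined: zero marginal")
    n <- sum(m)
    stat <- n * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
        (r[1] * r[2] * cl[1] * cl[2])
    data.frame(statistic = unname(stat), df = 1L,
               p = pchisq(unname(stat), df = 1L, lower.tail = FALSE))
}

#' One-sided Fisher's exact test on a 2x2 table
#'
#' Hypergeometric tail probability in the requested direction, with
#' the sample odds ratio \eqn{ad/(bc)} as the reported estimate (the
#' conditional MLE that \code{fisher.test} reports is deliberately not
#' used as the point estimate; the exact p-value is identical).
#'
#' @param table cell counts \code{c(a, b, c, d)} row-major, or 2x2
#'   matrix.
#' @param direction \code{"greater"} tests for enrichment of the first
#'   column in the first row; \code{"less"} the reverse.
#' @return data.frame with \code{p} and \code{estimate} (sample OR;
#'   \code{Inf}/\code{NaN} when cells are zero).
#' @export
fisherOneSided <- function(table, direction = c("greater", "less")) {
    direction <- match.arg(direction)
    m <- .as2x2(table)
    a <- m[1, 1]
    ## margins: first column total and row totals
    k <- sum(m[, 1]); r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
    p <- if (direction == "greater")
        phyper(a - 1, r1, r2, k, lower.tail = FALSE)
    else
        phyper(a, r1, r2, k)
    est <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
    data.frame(p = p, estimate = unname(est))
}

#' Odds ratio with Woolf (log) confidence interval
#'
#' \eqn{OR = ad/(bc)} with
#' \eqn{CI = \exp(\log OR \pm z \sqrt{1/a + 1/b + 1/c + 1/d})}.  When
#' any cell is zero, 0.5 is added to every cell (Haldane-Anscombe) and
#' the result flagged.
#'
#' @param table cell counts \code{c(a, b, c, d)} row-major, or 2x2
#'   matrix.
#' @param level confidence level (default 0.95).
#' @return data.frame with \code{estimate}, \code{ciLow},
#'   \code{ciHigh}, \code{corrected}.
#' @examples
#' oddsRatioWoolf(c(145, 88, 204, 152))  # ~1.23 (0.88, 1.72)
#' @export
oddsRatioWoolf <- function(table, level = 0.95) {
    m <- .as2x2(table)
    corrected <- any(m == 0)
    if (corrected) m <- m + 0.5
    or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
    se <- sqrt(sum(1 / m))
    z <- qnorm(1 - (1 - level) / 2)
    data.frame(estimate = or,
               ciLow = exp(log(or) - z * se),
               ciHigh = exp(log(or) + z * se),
               corrected = corrected)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Step-up FDR adjustment \eqn{q_i = \min_{j \ge i} p_{(j)} m / j}
#' capped at 1 and returned in input order.  \code{mTotal} may exceed
#' the number of p-values supplied, so q-values for a published top
#' list can be computed against the full genome-wide test count.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param mTotal total number of tests (default \code{length(p)}).
#' @return numeric vector of q-values, input order.
#' @examples
#' bhFdr(2.62e-11, mTotal = 536270)  # ~1.40e-5
#' @export
bhFdr <- function(p, mTotal = length(p)) {
    stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
    if (mTotal < length(p))
        stop("mTotal must be at least length(p)")
    p.adjust(p, method = "BH", n = mTotal)
}

#' Bonferroni adjustment
#'
#' Companion to \code{\link{bhFdr}} for the naive family-wise
#' correction: \code{pmin(1, p * mTotal)}.
#'
#' @inheritParams bhFdr
#' @return adjusted p-values in input order.
#' @export
bonferroniAdjust <- function(p, mTotal = length(p)) {
    if (mTotal < length(p))
        stop("mTotal must be at least length(p)")
    p.adjust(p, method = "bonferroni", n = mTotal)
}

#' Two-sample Student's t-test
#'
#' Pooled-variance Student's t by default (the classical test used for
#' all case-control burden and inbreeding contrasts), with Welch as an
#' option.  A degenerate comparison (zero pooled variance, equal
#' means) returns p = 1 flagged.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param alternative \code{"two.sided"}, \code{"greater"} (mean of
#'   \code{x} larger) or \code{"less"}.
#' @param varEqual pooled variance if TRUE (default).
#' @return data.frame with \code{statistic}, \code{df}, \code{p},
#'   \code{estimate} (mean difference), \code{degenerate}.
#' @export
twoSampleT <- function(x, y, alternative = c("two.sided", "greater", "less"),
                       varEqual = TRUE) {
    alternative <- match.arg(alternative)
    if (length(x) < 2L || length(y) < 2L)
        stop("each sample must have at least 2 observations")
    if (var(x) == 0 && var(y) == 0) {
        d <- mean(x) - mean(y)
        if (d == 0)
            return(data.frame(statistic = 0, df = length(x) + length(y) - 2L,
                              p = 1, estimate = 0, degenerate = TRUE))
        return(data.frame(statistic = sign(d) * Inf,
                          df = length(x) + length(y) - 2L,
                          p = switch(alternative,
                                     two.sided = 0,
                                     greater = if (d > 0) 0 else 1,
                                     less = if (d < 0) 0 else 1),
                          estimate = d, degenerate = TRUE))
    }
    tt <- t.test(x, y, alternative = alternative, var.equal = varEqual)
    data.frame(statistic = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, estimate = mean(x) - mean(y),
               degenerate = FALSE)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero
#'   variance.
#' @return data.frame with \code{estimate} (r), \code{statistic},
#'   \code{df}, \code{p}.
#' @export
pearsonCorr <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    ok <- complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L) stop("need at least 3 complete pairs")
    if (var(x) == 0 || var(y) == 0)
        stop("correlation undefined: zero variance")
    ct <- cor.test(x, y, method = "pearson")
    data.frame(estimate = unname(ct$estimate),
               statistic = unname(ct$statistic),
               df = unname(ct$parameter), p = ct$p.value)
}
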