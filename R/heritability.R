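## Genetic relationship matrices, principal components, AI-REML
## variance-component estimation and the liability-scale transform.

#' GRM: genetic relationship matrix
#'
#' Symmetric relatedness matrix estimated from standardized genotypes.
#' Off-diagonal entries average
#' \eqn{(x_{ij} - 2p_i)(x_{ik} - 2p_i)/(2 p_i q_i)} over SNPs
#' non-missing in both individuals; diagonal entries are
#' \eqn{1 + F3_j}, i.e. one plus the uniting-gamete correlation of the
#' individual, computed from the same frequencies.
#'
#' Slots: \code{matrix} (relatedness), \code{pairSnps} (per-pair SNP
#' counts), \code{m} (polymorphic SNPs used).
#'
#' @name GRM-class
#' @exportClass GRM
setClass("GRM", representation(matrix = "matrix", pairSnps = "matrix",
                               m = "integer"))

setValidity("GRM", function(object) {
    if (!isSymmetric(object@matrix, tol = 1e-8))
        return("GRM matrix must be symmetric")
    TRUE
})

setMethod("show", "GRM", function(object) {
    cat("GRM:", nrow(object@matrix), "samples,", object@m, "SNPs\n")
    cat("  mean diagonal:", format(mean(diag(object@matrix)), digits = 4),
        "\n")
})

#' @describeIn GRM-class relatedness matrix accessor
#' @param x a \code{GRM}.
#' @export
grmMatrix <- function(x) x@matrix

#' Compute a genetic relationship matrix
#'
#' Monomorphic SNPs are excluded; missing genotypes are handled by
#' per-pair complete-SNP normalization.  Allele frequencies come from
#' the full sample unless supplied.
#'
#' @param x a \linkS4class{GenotypeDataset} with >= 2 samples.
#' @param variantSubset optional logical/integer/character index of
#'   variants to use (e.g. one chromosome, or a post-exclusion set).
#' @param freq optional allele-B frequencies (full variant set,
#'   subset applied internally).
#' @return A \linkS4class{GRM}.
#' @export
computeGRM <- function(x, variantSubset = NULL, freq = NULL) {
    calls <- genotypeCalls(x)
    if (ncol(calls) < 2L) stop("GRM needs at least 2 samples")
    p <- if (is.null(freq)) .freqB(calls) else freq
    if (!is.null(variantSubset)) {
        if (is.character(variantSubset))
            variantSubset <- match(variantSubset, rownames(calls))
        calls <- calls[variantSubset, , drop = FALSE]
        p <- p[variantSubset]
    }
    usable <- !is.na(p) & p > 0 & p < 1
    if (!any(usable)) stop("all SNPs are monomorphic")
    xg <- calls[usable, , drop = FALSE]
    p <- p[usable]
    denom <- sqrt(2 * p * (1 - p))
    z <- (xg - 2 * p) / denom
    obs <- !is.na(z)
    z[!obs] <- 0
    cross <- crossprod(z)
    pairs <- crossprod(obs * 1L)
    A <- cross / pairs
    ## diagonal: 1 + F3 from the same frequencies
    t3 <- (xg^2 - (1 + 2 * p) * xg + 2 * p^2) / (2 * p * (1 - p))
    diag(A) <- 1 + colMeans(t3, na.rm = TRUE)
    A <- (A + t(A)) / 2
    dimnames(A) <- list(colnames(calls), colnames(calls))
    new("GRM", matrix = A, pairSnps = pairs, m = sum(usable))
}

#' Principal components of a GRM
#'
#' Top-k eigenvectors of the relatedness matrix (unit norm), with a
#' deterministic sign convention: in each eigenvector the entry of
#' largest magnitude is positive.  When the leading eigenvalues are
#' (near) equal the decomposition is flagged degenerate.
#'
#' @param grm a \linkS4class{GRM} or symmetric matrix.
#' @param k number of components (< number of samples).
#' @return list with \code{vectors} (n x k), \code{values} (length k),
#'   \code{degenerate}.
#' @export
grmPCA <- function(grm, k = 10L) {
    A <- if (is(grm, "GRM")) grmMatrix(grm) else grm
    if (!isSymmetric(unname(A), tol = 1e-8)) stop("GRM must be symmetric")
    if (k >= nrow(A)) stop("k must be smaller than the number of samples")
    e <- eigen(A, symmetric = TRUE)
    vec <- e$vectors[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {
        i <- which.max(abs(vec[, j]))
        if (vec[i, j] < 0) vec[, j] <- -vec[, j]
    }
    rownames(vec) <- rownames(A)
    vals <- e$values[seq_len(k)]
    list(vectors = vec, values = vals,
         degenerate = diff(range(e$values)) < 1e-8 * max(abs(e$values), 1))
}

#' Variance components by average-information REML
#'
#' Fits \eqn{y = X\beta + \sum_k g_k + e} with
#' \eqn{g_k \sim N(0, A_k \sigma^2_{g_k})},
#' \eqn{e \sim N(0, I\sigma^2_e)} by restricted maximum likelihood
#' using average-information updates with EM fallback steps whenever
#' an AI step would leave the parameter space or decrease the REML
#' log-likelihood.  Variance components are constrained to be
#' non-negative (floored at a small fraction of the phenotypic
#' variance).  A binary 0/1 phenotype is analysed as a quantitative
#' trait on the observed scale.  Standard errors come from the
#' inverse AI matrix at convergence; the SE of
#' \eqn{h^2 = \sum\sigma^2_g / (\sum\sigma^2_g + \sigma^2_e)} by the
#' delta method.
#'
#' @param y numeric response (binary 0/1 or quantitative).
#' @param grms a \linkS4class{GRM}, a matrix, or a list of either (one
#'   per genomic partition, e.g. per autosome).
#' @param X covariate matrix including an intercept; default
#'   intercept-only.
#' @param maxIter iteration cap (100).
#' @param tol convergence threshold on the log-likelihood change
#'   (1e-8).
#' @return list of class \code{varianceComponents}: \code{sigmaG}
#'   (vector), \code{sigmaE}, \code{h2Obs}, \code{seH2},
#'   \code{seComponents}, \code{loglik}, \code{converged},
#'   \code{iterations}, \code{trajectory}.
#' @export
remlFit <- function(y, grms, X = NULL, maxIter = 100L, tol = 1e-8) {
    if (is(grms, "GRM") || is.matrix(grms)) grms <- list(grms)
    As <- lapply(grms, function(g) if (is(g, "GRM")) grmMatrix(g) else g)
    n <- length(y)
    stopifnot(all(vapply(As, nrow, 0L) == n))
    if (is.null(X)) X <- matrix(1, n, 1)
    X <- as.matrix(X)
    if (qr(X)$rank < ncol(X)) stop("covariate matrix X is singular")
    nG <- length(As)
    vp <- var(y)
    theta <- rep(vp / (nG + 1), nG + 1)   # sigmaG_1..k, sigmaE
    floorV <- 1e-8 * vp
    Vs <- c(As, list(diag(n)))

    remlPieces <- function(theta) {
        V <- matrix(0, n, n)
        for (k in seq_along(Vs)) V <- V + theta[k] * Vs[[k]]
        ch <- tryCatch(chol(V), error = function(e) NULL)
        if (is.null(ch)) return(NULL)
        Vi <- chol2inv(ch)
        XtViX <- crossprod(X, Vi %*% X)
        chX <- tryCatch(chol(XtViX), error = function(e) NULL)
        if (is.null(chX)) return(NULL)
        XtViXi <- chol2inv(chX)
        ViX <- Vi %*% X
        P <- Vi - ViX %*% XtViXi %*% t(ViX)
        Py <- P %*% y
        ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) +
                      sum(y * Py))
        list(P = P, Py = Py, ll = ll)
    }

    pieces <- remlPieces(theta)
    if (is.null(pieces)) stop("initial variance matrix not positive definite")
    traj <- pieces$ll
    converged <- FALSE
    iter <- 0L
    while (iter < maxIter) {
        iter <- iter + 1L
        P <- pieces$P; Py <- pieces$Py
        nc <- length(theta)
        grad <- numeric(nc)
        VPy <- vector("list", nc)
        for (k in seq_len(nc)) {
            VPy[[k]] <- Vs[[k]] %*% Py
            grad[k] <- -0.5 * (sum(P * Vs[[k]]) - sum(Py * VPy[[k]]))
        }
        AI <- matrix(0, nc, nc)
        PVPy <- lapply(VPy, function(v) P %*% v)
        for (k in seq_len(nc))
            for (l in k:nc) {
                AI[k, l] <- 0.5 * sum(VPy[[k]] * PVPy[[l]])
                AI[l, k] <- AI[k, l]
            }
        step <- tryCatch(solve(AI, grad), error = function(e) NULL)
        newTheta <- if (is.null(step)) NULL else theta + step
        newPieces <- NULL
        if (!is.null(newTheta) && all(newTheta > 0)) {
            cand <- remlPieces(newTheta)
            if (!is.null(cand) && cand$ll >= pieces$ll - 1e-10)
                newPieces <- cand
        }
        if (is.null(newPieces)) {
            ## EM fallback: guaranteed uphill, keeps components positive
            newTheta <- theta
            for (k in seq_len(nc)) {
                trPV <- sum(P * Vs[[k]])
                newTheta[k] <- theta[k] +
                    (theta[k]^2 / n) * (sum(Py * VPy[[k]]) - trPV)
            }
            newTheta <- pmax(newTheta, floorV)
            newPieces <- remlPieces(newTheta)
            if (is.null(newPieces)) break
        }
        delta <- newPieces$ll - pieces$ll
        theta <- newTheta
        pieces <- newPieces
        traj <- c(traj, pieces$ll)
        if (abs(delta) < tol) { converged <- TRUE; break }
    }
    ## SEs from the inverse AI matrix at the solution
    P <- pieces$P; Py <- pieces$Py
    nc <- length(theta)
    AI <- matrix(0, nc, nc)
    VPy <- lapply(Vs, function(V) V %*% Py)
    PVPy <- lapply(VPy, function(v) P %*% v)
    for (k in seq_len(nc))
        for (l in k:nc) {
            AI[k, l] <- 0.5 * sum(VPy[[k]] * PVPy[[l]])
            AI[l, k] <- AI[k, l]
        }
    covTheta <- tryCatch(solve(AI), error = function(e)
        matrix(NA_real_, nc, nc))
    tot <- sum(theta)
    h2 <- sum(theta[seq_len(nG)]) / tot
    ## delta method: h2 = S/(S + sigmaE) with S = sum(sigmaG)
    S <- sum(theta[seq_len(nG)])
    grad_h2 <- c(rep((tot - S) / tot^2, nG), -S / tot^2)
    seH2 <- sqrt(max(0, drop(t(grad_h2) %*% covTheta %*% grad_h2)))
    out <- list(sigmaG = theta[seq_len(nG)], sigmaE = theta[nc],
                h2Obs = h2, seH2 = seH2,
                seComponents = sqrt(pmax(0, diag(covTheta))),
                loglik = pieces$ll, converged = converged,
                iterations = iter, trajectory = traj)
    class(out) <- "varianceComponents"
    out
}

#' @export
print.varianceComponents <- function(x, ...) {
    cat("REML variance components", if (!x$converged) "(NOT converged)",
        "\n")
    for (k in seq_along(x$sigmaG))
        cat(sprintf("  sigmaG[%d] = %.4f\n", k, x$sigmaG[k]))
    cat(sprintf("  sigmaE    = %.4f\n", x$sigmaE))
    cat(sprintf("  h2 (observed scale) = %.4f (SE %.4f)\n",
                x$h2Obs, x$seH2))
    invisible(x)
}

#' Liability-scale multiplier
#'
#' \eqn{K(1-K)/z^2} with \eqn{z = \phi(\Phi^{-1}(1-K))}: the factor
#' converting observed-scale (0/1) heritability to the liability
#' scale for a trait with population prevalence K.
#'
#' @param K prevalence in (0, 1).
#' @return the multiplier (symmetric in K and 1-K).
#' @export
liabilityMultiplier <- function(K) {
    if (K <= 0 || K >= 1) stop("K must be in (0, 1)")
    z <- dnorm(qnorm(1 - K))
    K * (1 - K) / z^2
}

#' Transform observed-scale heritability to the liability scale
#'
#' \eqn{h^2_l = h^2_o K(1-K)/z^2}.  With
#' \code{sampleCaseFraction} supplied, the case-control ascertainment
#' factor \eqn{K(1-K)/(P(1-P))} is additionally applied (off by
#' default: the plain transform is the published form).
#'
#' @param h2Obs observed-scale heritability (>= 0).
#' @param K population prevalence in (0, 1).
#' @param se optional SE of \code{h2Obs}, scaled by the same factor.
#' @param sampleCaseFraction optional case proportion P in the
#'   analysed sample, enabling the ascertainment correction.
#' @return list with \code{h2Liab}, \code{multiplier} and (when
#'   \code{se} given) \code{seLiab}.
#' @export
liabilityTransform <- function(h2Obs, K, se = NULL,
                               sampleCaseFraction = NULL) {
    if (h2Obs < 0) stop("h2Obs must be non-negative")
    mult <- liabilityMultiplier(K)
    if (!is.null(sampleCaseFraction)) {
        P <- sampleCaseFraction
        if (P <= 0 || P >= 1) stop("sampleCaseFraction must be in (0, 1)")
        mult <- mult * K * (1 - K) / (P * (1 - P))
    }
    out <- list(h2Liab = h2Obs * mult, multiplier = mult)
    if (!is.null(se)) out$seLiab <- se * mult
    out
}
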