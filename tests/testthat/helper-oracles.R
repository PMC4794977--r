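## Shared fixtures and independent brute-force oracles.  Every oracle
## here is deliberately written as plain loops, independent of the
## package's vectorized implementations.

## quick dataset builder from a variants x samples matrix
makeDataset <- function(calls, chrom = NULL, bp = NULL, phenotype = NULL,
                        sex = NULL) {
    calls <- as.matrix(calls)
    m <- nrow(calls); n <- ncol(calls)
    if (is.null(chrom)) chrom <- rep(1L, m)
    if (is.null(bp)) {
        bp <- integer(m)
        for (ch in unique(chrom)) {
            i <- which(chrom == ch)
            bp[i] <- seq_along(i) * 10000L
        }
    }
    if (is.null(phenotype)) phenotype <- rep(NA_integer_, n)
    if (is.null(sex)) sex <- rep("unknown", n)
    GenotypeDataset(calls,
                    variants = data.frame(id = sprintf("v%d", seq_len(m)),
                                          chrom = chrom, bp = bp,
                                          alleleA = "A", alleleB = "B"),
                    samples = data.frame(id = sprintf("s%d", seq_len(n)),
                                         sex = sex, phenotype = phenotype))
}

## independent bit-level .bed decoder (rawToBits path, per-call loop)
naiveBedDecode <- function(bedPath, nSamples, nVariants) {
    raw <- readBin(bedPath, "raw", n = file.size(bedPath))
    stopifnot(raw[1] == as.raw(0x6c), raw[2] == as.raw(0x1b),
              raw[3] == as.raw(0x01))
    body <- raw[-(1:3)]
    bpv <- (nSamples + 3) %/% 4
    out <- matrix(NA_integer_, nVariants, nSamples)
    for (v in seq_len(nVariants)) {
        bytes <- body[((v - 1) * bpv + 1):(v * bpv)]
        bits <- as.integer(rawToBits(bytes))
        for (s in seq_len(nSamples)) {
            b1 <- bits[2 * s - 1]; b2 <- bits[2 * s]
            code <- b1 + 2 * b2
            out[v, s] <- switch(code + 1L, 0L, NA_integer_, 1L, 2L)
        }
    }
    out
}

## brute-force ROH scan: explicit window loops, then run enumeration
oracleScanRoh <- function(ds, params = rohParams()) {
    calls <- genotypeCalls(ds)
    vi <- variantInfo(ds)
    res <- list()
    for (sid in colnames(calls)) {
        for (ch in unique(vi$chrom)) {
            idx <- which(vi$chrom == ch)
            g <- calls[idx, sid]
            pos <- vi$bp[idx]
            n <- length(g)
            het <- !is.na(g) & g == 1L
            mis <- is.na(g)
            W <- params$windowSnp
            elig <- rep(FALSE, n)
            if (n >= W) {
                for (i in seq_len(n)) {
                    nWin <- 0L; nHom <- 0L
                    for (s in seq_len(n - W + 1L)) {
                        if (s <= i && i <= s + W - 1L) {
                            nWin <- nWin + 1L
                            if (sum(het[s:(s + W - 1L)]) <= params$windowHet &&
                                sum(mis[s:(s + W - 1L)]) <= params$windowMissing)
                                nHom <- nHom + 1L
                        }
                    }
                    elig[i] <- nWin > 0L && nHom / nWin > params$windowThreshold
                }
            }
            ok <- elig & !het
            run <- integer(0)
            flush <- function(run) {
                if (length(run) == 0L) return(NULL)
                nSnp <- length(run)
                lk <- (pos[run[nSnp]] - pos[run[1L]] + 1) / 1000
                if (nSnp >= params$minSnp && lk >= params$minKb &&
                    lk / nSnp <= params$minDensityKbPerSnp)
                    data.frame(sampleId = sid, chrom = ch,
                               startBp = pos[run[1L]], endBp = pos[run[nSnp]],
                               nSnp = nSnp)
                else NULL
            }
            for (i in seq_len(n)) {
                if (ok[i]) {
                    if (length(run) &&
                        pos[i] - pos[run[length(run)]] >
                        params$maxGapKb * 1000) {
                        res[[length(res) + 1L]] <- flush(run)
                        run <- integer(0)
                    }
                    run <- c(run, i)
                } else if (length(run)) {
                    res[[length(res) + 1L]] <- flush(run)
                    run <- integer(0)
                }
            }
            if (length(run)) res[[length(res) + 1L]] <- flush(run)
        }
    }
    res <- res[!vapply(res, is.null, TRUE)]
    if (!length(res))
        return(data.frame(sampleId = character(), chrom = integer(),
                          startBp = numeric(), endBp = numeric(),
                          nSnp = integer()))
    out <- do.call(rbind, res)
    out[order(out$sampleId, out$chrom, out$startBp), , drop = FALSE]
}

## segment GRanges -> canonical data.frame for comparisons
segDf <- function(gr) {
    df <- data.frame(sampleId = S4Vectors::mcols(gr)$sampleId,
                     chrom = as.integer(as.character(
                         GenomicRanges::seqnames(gr))),
                     startBp = GenomicRanges::start(gr),
                     endBp = GenomicRanges::end(gr),
                     nSnp = S4Vectors::mcols(gr)$nSnp)
    df <- df[order(df$sampleId, df$chrom, df$startBp), , drop = FALSE]
    rownames(df) <- NULL
    df
}

## brute-force connected components of the interval-overlap graph
oraclePools <- function(df) {
    n <- nrow(df)
    comp <- seq_len(n)
    repeat {
        changed <- FALSE
        for (i in seq_len(n)) for (j in seq_len(n)) {
            if (df$chrom[i] == df$chrom[j] &&
                max(df$startBp[i], df$startBp[j]) <=
                min(df$endBp[i], df$endBp[j]) &&
                comp[i] != comp[j]) {
                comp[comp == comp[j]] <- comp[i]
                changed <- TRUE
            }
        }
        if (!changed) break
    }
    match(comp, unique(comp))
}

## naive BH step-up by the min-scan definition
oracleBH <- function(p, m) {
    o <- order(p)
    ps <- p[o]
    k <- length(p)
    q <- numeric(k)
    for (i in seq_len(k))
        q[i] <- min(1, min(ps[i:k] * m / (i:k)))
    q[order(o)]
}

## exhaustive one-sided Fisher p by enumerating the support
oracleFisherGreater <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; k <- a + c
    support <- max(0, k - r2):min(r1, k)
    probs <- vapply(support, function(x)
        choose(r1, x) * choose(r2, k - x) / choose(r1 + r2, k), 0)
    sum(probs[support >= a])
}
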