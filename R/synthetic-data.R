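## Synthetic case-control genotype cohorts with LD blocks, per-individual
## inbreeding, planted autozygous tracts and recessive disease loci.
## Haplotypes are drawn from a per-block founder pool; founder
## haplotypes themselves carry AR(1)-correlated alleles so that r^2
## within a block is substantial while marginal allele frequencies
## match the configured MAFs.  Autozygosity is introduced by copying
## one haplotype over the other across contiguous multi-block
## segments, so inbred genomes carry genuine multi-SNP homozygous
## tracts rather than independent per-SNP excess homozygosity.

#' Simulation configuration
#'
#' Validated parameter bundle for \code{\link{simulateGenotypes}}.
#' The default profile is desk-scale (200 cases / 200 controls, 20,000
#' SNPs on 4 chromosomes) and is shaped after a GWAS cohort of 649
#' cases / 431 controls with ~536k autosomal SNPs and ~35\% mean
#' heterozygosity; \code{mafRange = c(0.05, 0.5)} gives a mean
#' expected heterozygosity of ~0.36.
#'
#' @param nCases,nControls cohort sizes.
#' @param nSnps total SNPs (split evenly over chromosomes).
#' @param nChroms number of autosomes used (1..22).
#' @param snpSpacingBp mean inter-SNP spacing in bp.
#' @param mafRange allele-B frequency range, within (0, 0.5].
#' @param ldBlockSnps SNPs per LD block (haplotypes are exchanged at
#'   block granularity; r^2 across block boundaries is ~0).
#' @param founderHaplotypes founder pool size per block.
#' @param ldRho latent AR(1) correlation of alleles along a founder
#'   haplotype within a block.
#' @param inbreedingF autozygosity probability per genomic segment:
#'   a scalar, a named vector \code{c(cases =, controls =)}, or a
#'   per-individual vector of length \code{nCases + nControls}
#'   (the two latter forms require no recessive loci).
#' @param autoSegSnps length of an autozygosity segment in SNPs
#'   (rounded up to whole LD blocks); at the default spacing the
#'   default of 100 SNPs is a ~1.5 Mb tract.
#' @param plantedRoh optional data.frame of tracts to plant
#'   (\code{chrom}, \code{startBp}, \code{lengthKb},
#'   \code{carrierFracCases}, \code{carrierFracControls}).
#' @param recessiveLoci optional data.frame of risk loci
#'   (\code{variantIndex}, \code{orHom}): the log odds of disease
#'   increases by \code{log(orHom)} for individuals homozygous
#'   (either homozygote class) at the locus.
#' @param baselinePrevalence baseline disease probability.
#' @param missingRate per-call missing probability.
#' @param seed integer seed (stored; used by
#'   \code{\link{simulateGenotypes}}).
#' @return list of class \code{simConfig}.
#' @export
simConfig <- function(nCases = 200L, nControls = 200L, nSnps = 20000L,
                      nChroms = 4L, snpSpacingBp = 15000,
                      mafRange = c(0.05, 0.5), ldBlockSnps = 10L,
                      founderHaplotypes = 100L, ldRho = 0.95,
                      inbreedingF = 0, autoSegSnps = 100L,
                      plantedRoh = NULL, recessiveLoci = NULL,
                      baselinePrevalence = 0.2, missingRate = 0.001,
                      seed = 1L) {
    cfg <- as.list(environment())
    if (nCases < 1L || nControls < 1L || nSnps < 1L || nChroms < 1L)
        stop("all counts must be positive")
    if (nChroms > 22L) stop("at most 22 autosomes")
    if (mafRange[1] <= 0 || mafRange[2] > 0.5 || mafRange[1] > mafRange[2])
        stop("mafRange must lie within (0, 0.5]")
    if (any(inbreedingF < 0) || any(inbreedingF >= 1))
        stop("inbreedingF must be in [0, 1)")
    if (length(inbreedingF) > 1L && !is.null(recessiveLoci))
        stop("stratum/per-individual inbreedingF requires no recessive loci")
    if (baselinePrevalence <= 0 || baselinePrevalence >= 1)
        stop("baselinePrevalence must be in (0, 1)")
    if (!is.null(recessiveLoci))
        stopifnot(all(recessiveLoci$variantIndex >= 1L),
                  all(recessiveLoci$variantIndex <= nSnps))
    class(cfg) <- "simConfig"
    cfg
}

## variant map: jittered grid per chromosome
.simMap <- function(cfg) {
    perChrom <- rep(cfg$nSnps %/% cfg$nChroms, cfg$nChroms)
    perChrom[seq_len(cfg$nSnps %% cfg$nChroms)] <-
        perChrom[seq_len(cfg$nSnps %% cfg$nChroms)] + 1L
    maps <- lapply(seq_len(cfg$nChroms), function(ch) {
        m <- perChrom[ch]
        gaps <- pmax(1, round(cfg$snpSpacingBp * runif(m, 0.5, 1.5)))
        data.frame(chrom = ch, bp = 1e6 + cumsum(gaps))
    })
    map <- do.call(rbind, maps)
    map$id <- sprintf("snp%d_%d", map$chrom, map$bp)
    map$maf <- runif(nrow(map), cfg$mafRange[1], cfg$mafRange[2])
    map$alleleA <- "A"
    map$alleleB <- "B"
    map
}

## draw one founder pool: nF x bs binary matrix with AR(1) latent
.founderPool <- function(nF, p, rho) {
    bs <- length(p)
    z <- matrix(rnorm(nF * bs), nF, bs)
    if (bs > 1L)
        for (j in 2:bs)
            z[, j] <- rho * z[, j - 1L] + sqrt(1 - rho^2) * z[, j]
    h <- matrix(0L, nF, bs)
    for (j in seq_len(bs)) h[, j] <- as.integer(z[, j] <= qnorm(p[j]))
    h
}

## the founder population: one haplotype pool per LD block, drawn once
## per simulation so every ascertainment batch samples one population
.simFounders <- function(map, cfg) {
    lapply(unique(map$chrom), function(ch) {
        idx <- which(map$chrom == ch)
        nb <- ceiling(length(idx) / cfg$ldBlockSnps)
        blockOf <- rep(seq_len(nb), each = cfg$ldBlockSnps)[seq_along(idx)]
        pools <- lapply(seq_len(nb), function(b)
            .founderPool(cfg$founderHaplotypes, map$maf[idx[blockOf == b]],
                         cfg$ldRho))
        list(chrom = ch, idx = idx, nb = nb, blockOf = blockOf,
             pools = pools)
    })
}

## genotypes for nInd individuals with per-individual segment-level
## autozygosity probability fInd; returns calls (snps x ind) and the
## realized autozygous intervals
.simCohortRaw <- function(map, founders, cfg, fInd) {
    nInd <- length(fInd)
    calls <- matrix(0L, nrow(map), nInd)
    autoTruth <- list()
    blocksPerSeg <- max(1L, ceiling(cfg$autoSegSnps / cfg$ldBlockSnps))
    for (fo in founders) {
        ch <- fo$chrom
        idx <- fo$idx
        nb <- fo$nb
        blockOf <- fo$blockOf
        segOf <- (seq_len(nb) - 1L) %/% blocksPerSeg + 1L
        nSeg <- max(segOf)
        aut <- matrix(rbinom(nInd * nSeg, 1L, rep(fInd, nSeg)) == 1L,
                      nInd, nSeg)
        for (b in seq_len(nb)) {
            bi <- idx[blockOf == b]
            H <- fo$pools[[b]]
            i1 <- sample.int(cfg$founderHaplotypes, nInd, replace = TRUE)
            i2 <- sample.int(cfg$founderHaplotypes, nInd, replace = TRUE)
            copy <- aut[, segOf[b]]
            i2[copy] <- i1[copy]
            calls[bi, ] <- t(H[i1, , drop = FALSE] + H[i2, , drop = FALSE])
        }
        ## realized autozygous intervals (per individual, merged per run)
        for (ind in which(rowSums(aut) > 0)) {
            r <- rle(aut[ind, ])
            ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
            for (k in which(r$values)) {
                segSnps <- idx[segOf[blockOf] >= starts[k] &
                               segOf[blockOf] <= ends[k]]
                autoTruth[[length(autoTruth) + 1L]] <- data.frame(
                    indIndex = ind, chrom = ch,
                    startBp = map$bp[segSnps[1L]],
                    endBp = map$bp[segSnps[length(segSnps)]],
                    nSnp = length(segSnps))
            }
        }
    }
    if (cfg$missingRate > 0) {
        nMiss <- rbinom(1L, length(calls), cfg$missingRate)
        if (nMiss > 0)
            calls[sample.int(length(calls), nMiss)] <- NA_integer_
    }
    list(calls = calls,
         autozygous = if (length(autoTruth)) do.call(rbind, autoTruth)
                      else NULL)
}

.caseProb <- function(calls, cfg) {
    eta <- rep(qlogis(cfg$baselinePrevalence), ncol(calls))
    if (!is.null(cfg$recessiveLoci))
        for (i in seq_len(nrow(cfg$recessiveLoci))) {
            v <- cfg$recessiveLoci$variantIndex[i]
            hom <- !is.na(calls[v, ]) & calls[v, ] != 1L
            eta <- eta + log(cfg$recessiveLoci$orHom[i]) * hom
        }
    plogis(eta)
}

#' Simulate a case-control genotype cohort
#'
#' Generates a \linkS4class{GenotypeDataset} under \code{config}
#' together with a truth record.  With recessive risk loci, phenotypes
#' follow the logistic model of \code{\link{assignPhenotypes}} and
#' individuals are sampled batch-wise until the case and control
#' quotas are met (case-control ascertainment); without risk loci the
#' requested numbers of individuals are generated directly and labels
#' assigned at random (a null cohort).  Planted ROH tracts from the
#' config are applied last via \code{\link{plantAutozygosity}}.
#'
#' @param config a \code{\link{simConfig}}.
#' @param seed integer seed (defaults to \code{config$seed}).
#' @return list with \code{dataset} (a
#'   \linkS4class{GenotypeDataset}), and \code{truth}: \code{maf},
#'   \code{inbreedingF} (per individual), \code{autozygous} (realized
#'   autozygous intervals), \code{planted} (planted tract intervals),
#'   \code{riskLoci}, \code{caseProb}.
#' @export
simulateGenotypes <- function(config, seed = config$seed) {
    stopifnot(inherits(config, "simConfig"))
    set.seed(seed)
    map <- .simMap(config)
    founders <- .simFounders(map, config)
    nTotal <- config$nCases + config$nControls
    ascertain <- !is.null(config$recessiveLoci)
    if (!ascertain) {
        pheno <- sample(rep(c(1L, 0L), c(config$nCases, config$nControls)))
        fInd <- if (length(config$inbreedingF) == nTotal)
            config$inbreedingF
        else if (!is.null(names(config$inbreedingF)))
            ifelse(pheno == 1L, config$inbreedingF[["cases"]],
                   config$inbreedingF[["controls"]])
        else rep(config$inbreedingF, nTotal)
        raw <- .simCohortRaw(map, founders, config, fInd)
        calls <- raw$calls
        autoz <- raw$autozygous
        caseProb <- rep(config$baselinePrevalence, nTotal)
    } else {
        kept <- list(); keptAuto <- list(); keptF <- c(); keptP <- c()
        phenoKept <- c()
        need <- c(cases = config$nCases, controls = config$nControls)
        batch <- 0L
        while (any(need > 0)) {
            batch <- batch + 1L
            if (batch > 60L)
                stop("case/control quota unattainable under this config")
            nb <- nTotal
            raw <- .simCohortRaw(map, founders, config,
                                 rep(config$inbreedingF, nb))
            pr <- .caseProb(raw$calls, config)
            st <- rbinom(nb, 1L, pr)
            take <- which((st == 1L & need["cases"] > 0) |
                          (st == 0L & need["controls"] > 0))
            takeCases <- take[st[take] == 1L][seq_len(min(need["cases"],
                                         sum(st[take] == 1L)))]
            takeCtrls <- take[st[take] == 0L][seq_len(min(need["controls"],
                                         sum(st[take] == 0L)))]
            take <- c(takeCases, takeCtrls)
            if (!length(take)) next
            off <- length(phenoKept)
            kept[[batch]] <- raw$calls[, take, drop = FALSE]
            if (!is.null(raw$autozygous)) {
                au <- raw$autozygous[raw$autozygous$indIndex %in% take, ,
                                     drop = FALSE]
                if (nrow(au)) {
                    au$indIndex <- off + match(au$indIndex, take)
                    keptAuto[[batch]] <- au
                }
            }
            phenoKept <- c(phenoKept, st[take])
            keptP <- c(keptP, pr[take])
            need["cases"] <- need["cases"] - length(takeCases)
            need["controls"] <- need["controls"] - length(takeCtrls)
        }
        calls <- do.call(cbind, kept)
        autoz <- if (length(keptAuto)) do.call(rbind, keptAuto) else NULL
        pheno <- phenoKept
        caseProb <- keptP
        fInd <- rep(config$inbreedingF, nTotal)
    }
    sampleIds <- sprintf("ind%04d", seq_len(nTotal))
    colnames(calls) <- sampleIds
    if (!is.null(autoz)) {
        autoz$sampleId <- sampleIds[autoz$indIndex]
        autoz$indIndex <- NULL
    }
    ds <- GenotypeDataset(
        calls,
        variants = map[, c("id", "chrom", "bp", "alleleA", "alleleB")],
        samples = data.frame(id = sampleIds,
                             sex = sample(c("male", "female"), nTotal,
                                          replace = TRUE),
                             phenotype = pheno))
    planted <- NULL
    if (!is.null(config$plantedRoh)) {
        pl <- plantAutozygosity(ds, config$plantedRoh)
        ds <- pl$dataset
        planted <- pl$truth
    }
    list(dataset = ds,
         truth = list(maf = setNames(map$maf, map$id),
                      inbreedingF = setNames(fInd, sampleIds),
                      autozygous = autoz,
                      planted = planted,
                      riskLoci = config$recessiveLoci,
                      caseProb = setNames(caseProb, sampleIds)))
}

#' Plant autozygous tracts into a dataset
#'
#' Forces designated carriers to be fully homozygous across specified
#' intervals: every heterozygous call in the tract is replaced by a
#' homozygote drawn with the allele-B frequency of that SNP.  The SNPs
#' immediately flanking the tract are set heterozygous for carriers so
#' that the planted autozygous interval is exactly delimited and its
#' detected coordinates are identical across carriers.  Overlapping
#' tracts for one individual are merged with a warning.
#'
#' @param x a \linkS4class{GenotypeDataset}.
#' @param spec data.frame with columns \code{chrom}, \code{startBp},
#'   \code{lengthKb} and either a list/semicolon column
#'   \code{carriers} of sample ids or columns
#'   \code{carrierFracCases}, \code{carrierFracControls}.
#' @param delimit force heterozygous flanking SNPs (default TRUE).
#' @return list with \code{dataset} (modified) and \code{truth}
#'   (data.frame: sampleId, chrom, startBp, endBp, firstSnpBp,
#'   lastSnpBp, nSnp).
#' @export
plantAutozygosity <- function(x, spec, delimit = TRUE) {
    vi <- variantInfo(x)
    ph <- phenotypes(x)
    calls <- genotypeCalls(x)
    p <- .freqB(calls)
    truth <- list()
    for (i in seq_len(nrow(spec))) {
        ch <- spec$chrom[i]
        st <- spec$startBp[i]
        en <- st + spec$lengthKb[i] * 1000 - 1
        onCh <- which(vi$chrom == ch)
        if (!length(onCh) || st < min(vi$bp[onCh]) || en > max(vi$bp[onCh]))
            stop("planted tract ", i, " extends beyond chromosome ", ch)
        idx <- onCh[vi$bp[onCh] >= st & vi$bp[onCh] <= en]
        if (!length(idx)) stop("planted tract ", i, " contains no SNPs")
        carriers <- if (!is.null(spec$carriers)) {
            v <- spec$carriers[[i]]
            if (is.character(v) && length(v) == 1L && grepl(";", v))
                strsplit(v, ";")[[1]] else v
        } else {
            sid <- names(ph)
            cas <- sid[!is.na(ph) & ph == 1L]
            ctl <- sid[!is.na(ph) & ph == 0L]
            c(sample(cas, round(spec$carrierFracCases[i] * length(cas))),
              sample(ctl, round(spec$carrierFracControls[i] * length(ctl))))
        }
        for (sid in carriers) {
            g <- calls[idx, sid]
            het <- !is.na(g) & g == 1L
            if (any(het))
                calls[idx[het], sid] <-
                    2L * rbinom(sum(het), 1L, p[idx[het]])
            if (delimit) {
                before <- onCh[onCh < idx[1L]]
                after <- onCh[onCh > idx[length(idx)]]
                if (length(before)) calls[max(before), sid] <- 1L
                if (length(after)) calls[min(after), sid] <- 1L
            }
            truth[[length(truth) + 1L]] <- data.frame(
                sampleId = sid, chrom = ch, startBp = st, endBp = en,
                firstSnpBp = vi$bp[idx[1L]],
                lastSnpBp = vi$bp[idx[length(idx)]],
                nSnp = length(idx), stringsAsFactors = FALSE)
        }
    }
    truth <- do.call(rbind, truth)
    ## merge overlapping tracts per individual in the truth record
    merged <- list()
    for (sid in unique(truth$sampleId)) {
        tr <- truth[truth$sampleId == sid, , drop = FALSE]
        for (ch in unique(tr$chrom)) {
            tc <- tr[tr$chrom == ch, , drop = FALSE]
            tc <- tc[order(tc$startBp), , drop = FALSE]
            if (nrow(tc) > 1L &&
                any(tc$startBp[-1L] <= cummax(tc$endBp)[-nrow(tc)])) {
                warning("overlapping planted tracts for ", sid,
                        " on chromosome ", ch, " merged")
                ir <- IRanges::reduce(IRanges::IRanges(tc$startBp, tc$endBp))
                tc <- data.frame(sampleId = sid, chrom = ch,
                                 startBp = IRanges::start(ir),
                                 endBp = IRanges::end(ir),
                                 firstSnpBp = NA_real_,
                                 lastSnpBp = NA_real_, nSnp = NA_integer_,
                                 stringsAsFactors = FALSE)
            }
            merged[[length(merged) + 1L]] <- tc
        }
    }
    truth <- do.call(rbind, merged)
    se <- SummarizedExperiment::`assay<-`(x, "calls", value = calls)
    list(dataset = se, truth = truth)
}

#' Assign phenotypes under a recessive-risk logistic model
#'
#' \eqn{\mathrm{logit}\,P(\mathrm{case}) = \beta_0 + \sum_j
#' \log(OR_j)\,[x_j \ne 1]} with \eqn{\beta_0} the logit of the
#' baseline prevalence and the sum over configured recessive loci
#' (risk for either homozygote class, matching the homozygosity
#' association model).  Draws one Bernoulli status per
#' individual; no ascertainment is applied here.
#'
#' @param x a \linkS4class{GenotypeDataset}.
#' @param config a \code{\link{simConfig}} supplying
#'   \code{baselinePrevalence} and \code{recessiveLoci}.
#' @return list with \code{phenotype} (0/1 vector named by sample) and
#'   \code{caseProb}.
#' @export
assignPhenotypes <- function(x, config) {
    calls <- genotypeCalls(x)
    pr <- .caseProb(calls, config)
    st <- rbinom(ncol(calls), 1L, pr)
    list(phenotype = setNames(st, colnames(calls)),
         caseProb = setNames(pr, colnames(calls)))
}
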