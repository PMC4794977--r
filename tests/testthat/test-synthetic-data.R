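test_that("the same seed reproduces the cohort byte for byte", {
    cfg <- simConfig(nCases = 20L, nControls = 20L, nSnps = 600L,
                     nChroms = 2L, inbreedingF = 0.05, seed = 5L)
    a <- simulateGenotypes(cfg)
    b <- simulateGenotypes(cfg)
    expect_identical(genotypeCalls(a$dataset), genotypeCalls(b$dataset))
    expect_identical(phenotypes(a$dataset), phenotypes(b$dataset))
    expect_identical(a$truth$autozygous, b$truth$autozygous)
    c <- simulateGenotypes(cfg, seed = 6L)
    expect_false(identical(genotypeCalls(a$dataset),
                           genotypeCalls(c$dataset)))
})

test_that("generated datasets satisfy the container invariants", {
    sim <- simulateGenotypes(simConfig(nCases = 15L, nControls = 15L,
                                       nSnps = 400L, nChroms = 3L,
                                       missingRate = 0.01, seed = 8L))
    expect_true(validObject(sim$dataset))
    vi <- variantInfo(sim$dataset)
    expect_true(all(tapply(vi$bp, vi$chrom, function(v) !is.unsorted(v))))
    g <- genotypeCalls(sim$dataset)
    expect_true(all(g[!is.na(g)] %in% 0:2))
})

test_that("heterozygosity follows the inbreeding-adjusted expectation", {
    nF <- 100L
    for (F in c(0, 0.2)) {
        cfg <- simConfig(nCases = 1000L, nControls = 1000L, nSnps = 2000L,
                         nChroms = 2L, mafRange = c(0.3, 0.3),
                         founderHaplotypes = nF, inbreedingF = F,
                         missingRate = 0, seed = 11L + round(F * 100))
        sim <- simulateGenotypes(cfg)
        pv <- perVariantStats(sim$dataset)
        ## finite founder pools shrink expected 2pq by (1 - 1/nF)
        expected <- 2 * 0.3 * 0.7 * (1 - 1 / nF) * (1 - F)
        se <- sd(pv$hetRate) / sqrt(nrow(pv))
        expect_lt(abs(mean(pv$hetRate) - expected), 3 * se)
        expect_lt(abs(mean(pv$hetRate) - 2 * 0.3 * 0.7 * (1 - F)), 0.012)
    }
})

test_that("empirical allele frequencies track the configured MAFs", {
    cfg <- simConfig(nCases = 1000L, nControls = 1000L, nSnps = 2000L,
                     nChroms = 2L, missingRate = 0, seed = 17L)
    sim <- simulateGenotypes(cfg)
    pv <- perVariantStats(sim$dataset)
    maf <- sim$truth$maf
    ## two-stage sampling: founder pool then 2n haplotype draws
    se <- sqrt(maf * (1 - maf) / cfg$founderHaplotypes +
               maf * (1 - maf) / (2 * 2000))
    outside <- mean(abs(pv$freqB - maf) > 3 * se)
    expect_lt(outside, 0.015)
    expect_lt(abs(mean(pv$freqB - maf)), 0.005)
})

test_that("LD is strong within blocks and absent across them", {
    cfg <- simConfig(nCases = 300L, nControls = 300L, nSnps = 1000L,
                     nChroms = 1L, ldBlockSnps = 10L, missingRate = 0,
                     seed = 19L)
    sim <- simulateGenotypes(cfg)
    g <- genotypeCalls(sim$dataset)
    within <- vapply(seq(1, 900, by = 10), function(s)
        suppressWarnings(cor(g[s, ], g[s + 1, ]))^2, 0)
    across <- vapply(seq(10, 900, by = 10), function(s)
        suppressWarnings(cor(g[s, ], g[s + 1, ]))^2, 0)
    expect_gt(mean(within, na.rm = TRUE), 0.3)
    expect_lt(mean(across, na.rm = TRUE), 0.05)
})

test_that("planted tracts are recovered and identical across carriers", {
    cfg <- simConfig(nCases = 50L, nControls = 50L, nSnps = 4000L,
                     nChroms = 2L, seed = 23L)
    sim <- simulateGenotypes(cfg)
    vi <- variantInfo(sim$dataset)
    start <- vi$bp[vi$chrom == 1][200]
    carriers <- colnames(sim$dataset)[1:50]
    pl <- plantAutozygosity(sim$dataset,
                            data.frame(chrom = 1, startBp = start,
                                       lengthKb = 1600,
                                       carriers = I(list(carriers))))
    segs <- scanRoh(pl$dataset)
    df <- segDf(segs)
    hits <- df[df$chrom == 1 & df$startBp >= start &
               df$endBp <= start + 1600 * 1000, ]
    ## every carrier is recovered with one identical segment
    expect_setequal(hits$sampleId, carriers)
    expect_equal(length(unique(hits$startBp)), 1L)
    expect_equal(length(unique(hits$endBp)), 1L)
    ## the called tract loses at most 2 SNPs per side to window scoring
    planted <- pl$truth$nSnp[1]
    expect_gte(min(hits$nSnp), planted - 4L)
    ## common-ROH grouping finds one group with all carriers
    grp <- commonRohGroups(segs, minSnp = 75L)
    expect_equal(grp$size[1], 50L)
})

test_that("tract planting is exact about edge cases", {
    cfg <- simConfig(nCases = 10L, nControls = 10L, nSnps = 500L,
                     nChroms = 1L, seed = 29L)
    sim <- simulateGenotypes(cfg)
    vi <- variantInfo(sim$dataset)
    ## tract beyond the chromosome end errors
    expect_error(plantAutozygosity(sim$dataset,
                                   data.frame(chrom = 1,
                                              startBp = max(vi$bp) - 1000,
                                              lengthKb = 500,
                                              carriers = I(list("ind0001")))),
                 "beyond chromosome")
    ## overlapping tracts for one individual merge with a warning
    st <- vi$bp[100]
    spec <- data.frame(chrom = 1, startBp = c(st, st + 200 * 1000),
                       lengthKb = c(400, 400),
                       carriers = I(list("ind0001", "ind0001")))
    expect_warning(pl <- plantAutozygosity(sim$dataset, spec), "merged")
    expect_equal(nrow(pl$truth), 1L)
})

test_that("caller sensitivity on generously sized planted tracts is high", {
    cfg <- simConfig(nCases = 40L, nControls = 40L, nSnps = 5000L,
                     nChroms = 2L, seed = 31L)
    sim <- simulateGenotypes(cfg)
    vi <- variantInfo(sim$dataset)
    ids <- colnames(sim$dataset)
    ## one tract per individual at varied positions, all above
    ## (minSnp + 10, minKb + 200) in size
    starts1 <- vi$bp[vi$chrom == 1][seq(100, 2000, by = 220)]
    starts2 <- vi$bp[vi$chrom == 2][seq(100, 2000, by = 220)]
    spec <- data.frame(chrom = rep(c(1, 2), c(length(starts1),
                                              length(starts2))),
                       startBp = c(starts1, starts2),
                       lengthKb = 1700)
    spec <- spec[rep(seq_len(nrow(spec)), length.out = 40), ]
    spec$carriers <- I(as.list(ids[seq_len(40)]))
    pl <- plantAutozygosity(sim$dataset, spec)
    segs <- segDf(scanRoh(pl$dataset))
    found <- vapply(seq_len(40), function(i) {
        tr <- pl$truth[pl$truth$sampleId == ids[i], ]
        any(segs$sampleId == ids[i] & segs$chrom == tr$chrom &
            segs$startBp >= tr$startBp & segs$endBp <= tr$endBp &
            segs$nSnp >= 75)
    }, TRUE)
    expect_gte(mean(found), 0.95)
})

test_that("phenotype assignment follows the recessive logistic model", {
    cfg <- simConfig(nCases = 500L, nControls = 500L, nSnps = 300L,
                     nChroms = 1L, baselinePrevalence = 0.5,
                     missingRate = 0, seed = 37L)
    sim <- simulateGenotypes(cfg)
    ph <- assignPhenotypes(sim$dataset, cfg)
    expect_equal(unname(ph$caseProb), rep(0.5, 1000))
    expect_lt(abs(mean(ph$phenotype) - 0.5), 3 * sqrt(0.25 / 1000))
    ## risk loci shift carrier probabilities by the configured log-odds
    cfg2 <- simConfig(nCases = 10L, nControls = 10L, nSnps = 300L,
                      nChroms = 1L, baselinePrevalence = 0.2,
                      recessiveLoci = data.frame(variantIndex = 7L,
                                                 orHom = 3),
                      seed = 41L)
    pr <- assignPhenotypes(sim$dataset, cfg2)$caseProb
    hom <- genotypeCalls(sim$dataset)[7, ] != 1L
    expect_equal(unique(round(pr[hom], 10)),
                 round(plogis(qlogis(0.2) + log(3)), 10))
    expect_equal(unique(round(pr[!hom], 10)), 0.2)
})

test_that("ascertainment fills quotas or fails loudly", {
    cfg <- simConfig(nCases = 80L, nControls = 80L, nSnps = 200L,
                     nChroms = 1L, baselinePrevalence = 0.3,
                     recessiveLoci = data.frame(variantIndex = 5L,
                                                orHom = 2),
                     seed = 43L)
    sim <- simulateGenotypes(cfg)
    ph <- phenotypes(sim$dataset)
    expect_equal(sum(ph == 1L), 80L)
    expect_equal(sum(ph == 0L), 80L)
    bad <- simConfig(nCases = 500L, nControls = 10L, nSnps = 50L,
                     nChroms = 1L, baselinePrevalence = 0.001,
                     recessiveLoci = data.frame(variantIndex = 2L,
                                                orHom = 1.1),
                     seed = 47L)
    expect_error(simulateGenotypes(bad), "unattainable")
})
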