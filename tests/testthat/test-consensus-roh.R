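mkSegs <- function(...) rohSegments(data.frame(...))

test_that("pooling groups by transitive overlap and nothing else", {
    ## disjoint segments: two singleton pools
    s <- mkSegs(sampleId = c("a", "b"), chrom = 1,
                startBp = c(1e6, 5e6), endBp = c(2e6, 6e6))
    p <- poolOverlapping(s)
    expect_equal(length(unique(S4Vectors::mcols(p)$poolId)), 2L)
    ## chain A-B-C with A and C disjoint: one pool of three
    s2 <- mkSegs(sampleId = c("a", "b", "c"), chrom = 1,
                 startBp = c(1e6, 1.8e6, 2.6e6),
                 endBp = c(2e6, 2.8e6, 3.6e6))
    p2 <- poolOverlapping(s2)
    expect_equal(length(unique(S4Vectors::mcols(p2)$poolId)), 1L)
    ## identical segments in 10 samples: one pool with 10 members
    s3 <- mkSegs(sampleId = sprintf("i%d", 1:10), chrom = 2,
                 startBp = 1e6, endBp = 2e6)
    p3 <- poolOverlapping(s3)
    expect_equal(unname(table(S4Vectors::mcols(p3)$poolId)[1]), 10L)
    ## bookended segments (no shared bp) are not pooled
    s4 <- mkSegs(sampleId = c("a", "b"), chrom = 1,
                 startBp = c(1e6, 2000001), endBp = c(2e6, 3e6))
    expect_equal(length(unique(S4Vectors::mcols(poolOverlapping(s4))$poolId)),
                 2L)
})

test_that("pooling matches the brute-force component oracle, any order", {
    set.seed(43)
    for (k in 1:8) {
        n <- sample(5:40, 1)
        df <- data.frame(sampleId = sprintf("i%d", sample(1:15, n, TRUE)),
                         chrom = sample(1:3, n, TRUE),
                         startBp = sample(1e6:2e7, n))
        df$endBp <- df$startBp + sample(1e5:3e6, n)
        segs <- mkSegs(sampleId = df$sampleId, chrom = df$chrom,
                       startBp = df$startBp, endBp = df$endBp)
        got <- S4Vectors::mcols(poolOverlapping(segs))$poolId
        want <- oraclePools(df)
        ## same partition (pool labels may differ)
        expect_equal(length(unique(got)), length(unique(want)))
        expect_true(all(tapply(got, want, function(v)
            length(unique(v))) == 1))
        ## order invariance
        o <- sample(n)
        got2 <- S4Vectors::mcols(poolOverlapping(segs[o]))$poolId
        expect_true(all(tapply(got2, want[o], function(v)
            length(unique(v))) == 1))
        ## every segment belongs to exactly one pool
        expect_true(all(got >= 1))
        expect_equal(length(got), n)
    }
})

test_that("consensus regions reproduce published interval lengths", {
    ## recurrent region on chromosome 3: 672 kb
    s <- mkSegs(sampleId = c("a", "b"), chrom = 3,
                startBp = c(120900000, 121016843),
                endBp = c(121689105, 121800000))
    pools <- consensusRegions(poolOverlapping(s))
    expect_equal(pools$consensusStart, 121016843)
    expect_equal(pools$consensusEnd, 121689105)
    expect_equal(pools$consensusKb, 672, tolerance = 0.001)
    ## chromosome 10 region: 959 kb
    s2 <- mkSegs(sampleId = "a", chrom = 10, startBp = 44969326,
                 endBp = 45928700)
    expect_equal(consensusRegions(poolOverlapping(s2))$consensusKb, 959,
                 tolerance = 0.001)
    ## identical member intervals: consensus equals the interval
    s3 <- mkSegs(sampleId = c("a", "b", "c"), chrom = 1,
                 startBp = 5e6, endBp = 6e6)
    p3 <- consensusRegions(poolOverlapping(s3))
    expect_equal(p3$consensusStart, 5e6)
    expect_equal(p3$consensusEnd, 6e6)
})

test_that("consensus bounds are within every member; empty ones flagged", {
    set.seed(47)
    df <- data.frame(sampleId = sprintf("i%d", 1:30), chrom = 1,
                     startBp = sample(1e6:5e6, 30))
    df$endBp <- df$startBp + sample(5e5:4e6, 30)
    segs <- poolOverlapping(mkSegs(sampleId = df$sampleId, chrom = df$chrom,
                                   startBp = df$startBp, endBp = df$endBp))
    pools <- consensusRegions(segs)
    pid <- S4Vectors::mcols(segs)$poolId
    for (i in seq_len(nrow(pools))) {
        if (!pools$nonEmpty[i]) next
        members <- which(pid == pools$poolId[i])
        expect_gte(pools$consensusStart[i],
                   max(GenomicRanges::start(segs)[members]) - 0)
        expect_lte(pools$consensusEnd[i],
                   min(GenomicRanges::end(segs)[members]))
    }
    ## a transitive chain with empty strict intersection is flagged
    chain <- mkSegs(sampleId = c("a", "b", "c"), chrom = 1,
                    startBp = c(1e6, 1.9e6, 2.8e6),
                    endBp = c(2e6, 2.9e6, 3.8e6))
    pc <- consensusRegions(poolOverlapping(chain))
    expect_false(pc$nonEmpty)
    expect_true(is.na(pc$consensusKb))
    expect_equal(nrow(filterRecurrent(pc, minSamples = 1, minKb = 0)), 0L)
})

test_that("consensus SNP and carrier counts come from the dataset", {
    ds <- makeDataset(matrix(0L, 50, 4), bp = seq_len(50) * 1e5,
                      phenotype = c(1L, 1L, 0L, NA))
    segs <- mkSegs(sampleId = c("s1", "s2", "s3", "s4"), chrom = 1,
                   startBp = c(1e6, 1.2e6, 1.1e6, 1.4e6),
                   endBp = c(3e6, 3.2e6, 3.1e6, 3.4e6))
    pools <- consensusRegions(poolOverlapping(segs), ds)
    expect_equal(pools$nSamples, 4L)
    expect_equal(pools$nCases, 2L)     # missing phenotype carrier excluded
    expect_equal(pools$nControls, 1L)
    ## SNPs at 1.4e6..3.0e6 inclusive on the 1e5 grid
    expect_equal(pools$nSnp, sum(seq_len(50) * 1e5 >= 1.4e6 &
                                 seq_len(50) * 1e5 <= 3e6))
})

test_that("recurrent filtering applies both thresholds and is idempotent", {
    pools <- data.frame(poolId = 1:4, chrom = 1,
                        consensusStart = 1e6,
                        consensusEnd = 1e6 + c(600000, 499900, 600000,
                                               499000) - 1,
                        consensusKb = c(600, 499.9, 600, 499),
                        nSegments = c(6L, 7L, 5L, 9L),
                        nSamples = c(6L, 7L, 5L, 9L),
                        nonEmpty = TRUE)
    keep <- filterRecurrent(pools)
    expect_equal(keep$poolId, 1L)      # pool 2 too short, pool 3 five samples
    expect_identical(filterRecurrent(keep), keep)
    ## brute force over random pools
    set.seed(53)
    rp <- data.frame(poolId = 1:50, chrom = 1, consensusStart = 0,
                     consensusEnd = 0,
                     consensusKb = runif(50, 300, 700),
                     nSegments = 1L,
                     nSamples = sample(3:9, 50, TRUE), nonEmpty = TRUE)
    got <- filterRecurrent(rp)$poolId
    want <- rp$poolId[rp$nSamples >= 6 & rp$consensusKb >= 500]
    expect_equal(got, want)
})

test_that("common-ROH groups require exact coordinate identity", {
    segs <- mkSegs(sampleId = c("a", "b", "c", "d", "e"), chrom = 1,
                   startBp = c(1e6, 1e6, 1e6, 1e6 + 1, 5e6),
                   endBp = c(2e6, 2e6, 2e6, 2e6, 6e6))
    S4Vectors::mcols(segs)$nSnp <- c(80L, 80L, 80L, 80L, 80L)
    g <- commonRohGroups(segs)
    expect_equal(nrow(g), 3L)
    expect_equal(g$size[1], 3L)        # a, b, c share coordinates exactly
    expect_equal(sum(g$size > 1), 1L)  # the 1-bp-shifted segment is alone
    ## minSnp filter
    S4Vectors::mcols(segs)$nSnp <- c(80L, 80L, 74L, 80L, 80L)
    g2 <- commonRohGroups(segs, minSnp = 75L)
    expect_equal(g2$size[1], 2L)
    ## all unique: no multi-member groups
    u <- mkSegs(sampleId = c("a", "b"), chrom = 1,
                startBp = c(1e6, 4e6), endBp = c(2e6, 5e6))
    S4Vectors::mcols(u)$nSnp <- c(90L, 90L)
    expect_equal(sum(commonRohGroups(u)$size > 1), 0L)
})

test_that("carrier association reproduces published chi-squares", {
    t3 <- data.frame(nCases = c(6, 10), nControls = c(15, 0))
    res <- carrierAssociation(t3, 649, 431)
    expect_equal(res$chi2, c(8.87, 6.70), tolerance = 0.01)
    flat <- carrierAssociation(data.frame(nCases = 30, nControls = 20),
                               300, 200)
    expect_equal(flat$chi2, 0)
    none <- carrierAssociation(data.frame(nCases = 0, nControls = 0),
                               649, 431)
    expect_false(none$testable)
    expect_error(carrierAssociation(data.frame(nCases = 700, nControls = 0),
                                    649, 431), "exceed")
})

test_that("per-SNP homozygosity proportion test is one-tailed toward cases", {
    set.seed(59)
    ## identical distributions: t = 0 and one-tailed p = 0.5
    half <- matrix(rbinom(20 * 30, 2, runif(20, 0.2, 0.8)), 20, 30)
    ds <- makeDataset(cbind(half, half), bp = seq_len(20) * 1e5,
                      phenotype = rep(c(1L, 0L), each = 30))
    r <- homozygosityProportionTest(ds, 1, 1e5, 2e6)
    expect_equal(r$p, 0.5)
    ## case-enriched homozygosity in the region drives p below 0.05
    cas <- matrix(rbinom(20 * 40, 2, 0.5), 20, 40)
    cas[, 1:25] <- ifelse(cas[, 1:25] == 1L, 0L, cas[, 1:25])
    ctl <- matrix(rbinom(20 * 40, 2, 0.5), 20, 40)
    ds2 <- makeDataset(cbind(cas, ctl), bp = seq_len(20) * 1e5,
                       phenotype = rep(c(1L, 0L), each = 40))
    r2 <- homozygosityProportionTest(ds2, 1, 1e5, 2e6)
    expect_lt(r2$p, 0.05)
    ## swapped labels reverse the direction
    ds3 <- makeDataset(cbind(cas, ctl), bp = seq_len(20) * 1e5,
                       phenotype = rep(c(0L, 1L), each = 40))
    expect_gt(homozygosityProportionTest(ds3, 1, 1e5, 2e6)$p, 0.5)
    expect_error(homozygosityProportionTest(ds2, 1, 1e5, 1.5e5),
                 "at least 2")
})
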