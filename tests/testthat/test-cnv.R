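.cnvGenome <- local({
    val <- NULL
    function() {
        if (is.null(val))
            val <<- simulateReferenceGenome(1, 1e5, subtelomereSpan = 33000,
                                            orfDensity = 0,
                                            repeatDensity = 0, seed = 71)
        val
    }
})

mkTrack <- function(depth, window = 500L, chrom = "chr01", ...) {
    starts <- seq.int(1L, by = window, length.out = length(depth))
    windowedLog2Depth(data.frame(chrom = chrom, start = starts,
                                 end = starts + window - 1L,
                                 depth = depth), ...)
}

test_that("normalization is exact for uniform depth and scale-invariant", {
    t1 <- mkTrack(rep(30, 100))
    expect_true(all(mcols(depthWindows(t1))$log2_ratio == 0))
    ## doubling all depths leaves log2 ratios unchanged
    set.seed(72)
    d <- rpois(200, 30)
    a <- mkTrack(d); b <- mkTrack(2 * d)
    expect_equal(mcols(depthWindows(a))$log2_ratio,
                 mcols(depthWindows(b))$log2_ratio, tolerance = 1e-12)
})

test_that("strains below 8x mapped coverage are rejected", {
    expect_error(mkTrack(rep(5, 50)), "below 8")
})

test_that("zero-coverage windows land on the log2 floor", {
    d <- rep(30, 60); d[10:20] <- 0
    t <- mkTrack(d, log2Floor = -10)
    expect_true(all(mcols(depthWindows(t))$log2_ratio[10:20] == -10))
})

test_that("masked windows never enter normalization or calls", {
    d <- rep(30, 100); d[41:60] <- 240     # repeat pile-up
    mask <- GRanges("chr01", IRanges(20001, 30000))
    t <- mkTrack(d, mask = mask)
    expect_equal(medianDepth(t), 30)
    expect_true(all(mcols(depthWindows(t))$masked[41:60]))
    t2 <- mkTrack(rep(30, 100), mask = mask)
    seg <- segmentCnv(list(a = t, b = t2))
    expect_equal(nrow(seg$calls), 0L)
})

test_that("a simulated copy-2 segment is called and overlaps truth", {
    g <- .cnvGenome()
    cn <- data.frame(chrom = "chr01", start = 40001, end = 45000,
                     copies = 2)
    trA <- simulateCoverage(g, cn, meanDepth = 30, noise = 0.02,
                            strain = "a", seed = 73)
    trB <- simulateCoverage(g, NULL, meanDepth = 30, noise = 0.02,
                            strain = "b", seed = 74)
    wa <- depthWindows(trA)
    inside <- start(wa) >= 40001 & end(wa) <= 45000
    expect_lt(abs(mean(mcols(wa)$log2_ratio[inside]) - 1), 0.2)
    seg <- segmentCnv(list(a = trA, b = trB))
    gain <- seg$calls[seg$calls$direction == "gain", ]
    expect_gte(nrow(gain), 1L)
    gr <- GenomicRanges::reduce(GRanges(gain$chrom,
                                        IRanges(gain$start, gain$end)))
    ov <- sum(width(GenomicRanges::intersect(
        gr, GRanges("chr01", IRanges(40001, 45000)))))
    expect_gte(ov / 5000, 0.8)
    ## no spurious calls far from the truth segment
    expect_lte(sum(width(gr)) - ov, 1500)
    ## segmentation is invariant to strain order
    seg2 <- segmentCnv(list(b = trB, a = trA))
    expect_equal(seg$totalAffected, seg2$totalAffected)
})

test_that("single-window excursions and shared CNV produce no variable region", {
    d <- rep(30, 100); d[50] <- 90
    a <- mkTrack(d); b <- mkTrack(rep(30, 100))
    expect_equal(nrow(segmentCnv(list(a = a, b = b))$calls), 0L)
    ## identical copy change in both strains: calls but no inter-strain
    ## variable region
    d2 <- rep(30, 100); d2[40:50] <- 60
    a2 <- mkTrack(d2); b2 <- mkTrack(d2)
    seg <- segmentCnv(list(a = a2, b = b2))
    expect_gt(nrow(seg$calls), 0L)
    expect_equal(seg$totalAffected, 0)
})

test_that("gene-family copy number aggregates member depth", {
    members <- GRanges("chr01", IRanges(c(10001, 30001), c(12000, 32000)))
    d <- rep(30, 100)
    t0 <- mkTrack(d)
    expect_equal(geneFamilyCopyNumber(t0, members), 2, tolerance = 1e-9)
    d1 <- d; d1[21:24] <- 0                 # first member deleted
    expect_equal(geneFamilyCopyNumber(mkTrack(d1), members), 1,
                 tolerance = 1e-9)
})

test_that("family estimates track truth across 1-12 copies at 30x", {
    g <- .cnvGenome()
    members <- GRanges("chr01", IRanges(c(20001, 60001), c(24000, 64000)))
    truthCopies <- c(1, 2, 4, 6, 9, 12)
    est <- vapply(seq_along(truthCopies), function(i) {
        k <- truthCopies[i]
        ## split the family copies across the two loci
        k1 <- ceiling(k / 2); k2 <- k - k1
        cn <- data.frame(chrom = "chr01",
                         start = c(20001, 60001), end = c(24000, 64000),
                         copies = c(k1, k2))
        tr <- simulateCoverage(g, cn, meanDepth = 30, noise = 0.02,
                               seed = 80 + i)
        geneFamilyCopyNumber(tr, members)
    }, 0)
    expect_true(all(abs(est - truthCopies) <= 1.0))
    sl <- coef(lm(est ~ truthCopies))[2L]
    expect_gt(sl, 0.9); expect_lt(sl, 1.1)
})

test_that("subtelomeric enrichment statistics behave at the null and extremes", {
    g <- .cnvGenome()   # 100 kb, subtelomeres 2 x 33 kb, core 34 kb
    ## uniformly placed variable regions: fold near 1
    set.seed(85)
    folds <- replicate(8, {
        s <- sort(sample.int(99000, 12))
        vr <- GenomicRanges::reduce(GRanges("chr01",
                                            IRanges(s, s + 800)))
        subtelomericEnrichment(vr, g)$fold
    })
    expect_lt(abs(mean(folds) - 1), 0.35)
    ## all CNV in subtelomeres: infinite fold sentinel
    vrSub <- GRanges("chr01", IRanges(1000, 5000))
    e <- subtelomericEnrichment(vrSub, g)
    expect_identical(e$fold, Inf)
    expect_equal(e$fraction_core, 0)
})

test_that("generator-level subtelomeric CNV enrichment is measured in range", {
    folds <- vapply(1:3, function(s) {
        g <- simulateReferenceGenome(2, 2e5, subtelomereSpan = 33000,
                                     orfDensity = 0, repeatDensity = 0,
                                     seed = 90 + s)
        pop <- simulatePopulation(g, starTree(4, 2e-3),
                                  rates = list(snp = 0, indel = 0,
                                               gain = 0, loss = 0,
                                               cnv = 1.2e-3, lof = 0),
                                  cnvLengthRange = c(2000, 5000),
                                  subtelEnrichment = 40, seed = 95 + s)
        tracks <- lapply(names(pop$genomes), function(st) {
            cn <- pop$truth$copy_numbers
            cn <- cn[cn$strain == st, , drop = FALSE]
            simulateCoverage(g, cn, meanDepth = 30, noise = 0.02,
                             strain = st, seed = 200 + s)
        })
        names(tracks) <- names(pop$genomes)
        seg <- segmentCnv(tracks)
        subtelomericEnrichment(seg$variableRegions, g)$fold
    }, 0)
    expect_true(all(folds >= 10))
})
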