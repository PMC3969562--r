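test_that("neighbor joining recovers additive 4-taxon trees exactly", {
    set.seed(51)
    for (i in 1:10) {
        ## additive matrix from a random quartet with positive branches
        e <- runif(5, 0.5, 3)  # a, b, c, d, internal
        dm <- matrix(0, 4, 4,
                     dimnames = list(letters[1:4], letters[1:4]))
        dm["a", "b"] <- dm["b", "a"] <- e[1] + e[2]
        dm["c", "d"] <- dm["d", "c"] <- e[3] + e[4]
        dm["a", "c"] <- dm["c", "a"] <- e[1] + e[5] + e[3]
        dm["a", "d"] <- dm["d", "a"] <- e[1] + e[5] + e[4]
        dm["b", "c"] <- dm["c", "b"] <- e[2] + e[5] + e[3]
        dm["b", "d"] <- dm["d", "b"] <- e[2] + e[5] + e[4]
        tr <- neighborJoining(dm)
        expect_identical(quartetSplit(tr), "a,b")
        expect_identical(quartetSplit(tr), bruteForceQuartetOracle(dm))
        ## branch lengths of an additive matrix are recovered exactly
        dd <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
        expect_equal(dd, dm, tolerance = 1e-10)
    }
})

test_that("3-taxon trees use the closed-form branch lengths", {
    dm <- matrix(c(0, 5, 9, 5, 0, 8, 9, 8, 0), 3,
                 dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
    tr <- neighborJoining(dm)
    ## three-point formulas: bx = (dxy + dxz - dyz)/2, etc.
    want <- c(x = (5 + 9 - 8) / 2, y = (5 + 8 - 9) / 2,
              z = (9 + 8 - 5) / 2)
    got <- setNames(tr$edge.length[match(seq_len(3),
                                         tr$edge[, 2L])][
        match(c("x", "y", "z"), tr$tip.label)],
        c("x", "y", "z"))
    got <- vapply(c("x", "y", "z"), function(t) {
        tip <- match(t, tr$tip.label)
        tr$edge.length[tr$edge[, 2L] == tip]
    }, 0)
    expect_equal(got, want)
})

test_that("6-taxon additive trees are recovered up to isomorphism", {
    set.seed(52)
    for (i in 1:5) {
        tr0 <- ape::rtree(6)
        tr0$edge.length <- runif(nrow(tr0$edge), 0.5, 2)
        dm <- ape::cophenetic.phylo(tr0)
        tr <- neighborJoining(dm)
        expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr0), tr)), 0)
        ## invariance under taxon reordering
        perm <- sample(6)
        tr2 <- neighborJoining(dm[perm, perm])
        expect_equal(as.numeric(ape::dist.topo(tr, tr2)), 0)
    }
})

test_that("ultrametric matrices give the single-linkage topology", {
    ## clean two-clade ultrametric structure
    lab <- c("a1", "a2", "b1", "b2", "b3")
    dm <- matrix(6, 5, 5, dimnames = list(lab, lab))
    dm[1:2, 1:2] <- 2; dm[3:5, 3:5] <- 2
    dm[3, 4] <- dm[4, 3] <- 1
    diag(dm) <- 0
    tr <- neighborJoining(dm)
    hc <- hclust(as.dist(dm), method = "single")
    ## the {a1,a2} | {b1,b2,b3} bipartition from single linkage is a
    ## split of the NJ tree
    sub <- ape::extract.clade(ape::root(tr, "a1"),
                              ape::getMRCA(ape::root(tr, "a1"),
                                           c("b1", "b2", "b3")))
    expect_setequal(sub$tip.label, c("b1", "b2", "b3"))
    expect_equal(unname(sort(cutree(hc, 2)[lab])), c(1, 1, 2, 2, 2))
})

test_that("the additive model matches the closed-form variance explained", {
    ## noiseless: R2 = 1 and exact coefficients
    copies <- rep(0:3, each = 5)
    y <- 2 + 1.5 * copies
    fit <- additiveCnModel(copies, y)
    expect_equal(fit$varianceExplained, 1)
    expect_equal(fit$slope, 1.5)
    expect_equal(fit$intercept, 2)
    expect_equal(unname(fit$groupMeans), c(2, 3.5, 5, 6.5))
    ## R2 equals squared Pearson correlation (single-predictor identity)
    set.seed(53)
    copies <- sample(0:3, 40, replace = TRUE)
    y <- 1 + 0.8 * copies + rnorm(40, 0, 0.7)
    fit2 <- additiveCnModel(copies, y)
    expect_equal(fit2$varianceExplained, cor(copies, y)^2,
                 tolerance = 1e-10)
    ## noisy generator recovers R2 near beta^2 Var(c)/(beta^2 Var(c)+s^2)
    beta <- 1; sigma <- 0.5
    r2s <- vapply(1:20, function(s) {
        cc <- sample(0:3, 100, replace = TRUE)
        ph <- simulatePhenotypes(
            data.frame(strain = sprintf("s%d", 1:100), copies = cc),
            slope = beta, noiseSD = sigma, seed = 600 + s)
        additiveCnModel(ph$copies, ph$phenotype)$varianceExplained
    }, 0)
    cc <- sample(0:3, 1e5, replace = TRUE)
    want <- beta^2 * var(cc) / (beta^2 * var(cc) + sigma^2)
    expect_lt(abs(mean(r2s) - want), 0.03)
})

test_that("association p-values are uniform under permutation", {
    set.seed(54)
    copies <- sample(0:3, 40, replace = TRUE)
    y <- rnorm(40)
    ps <- replicate(500, additiveCnModel(copies, sample(y))$p)
    expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("model preconditions are enforced", {
    expect_error(additiveCnModel(c(1, 2), c(1, 2)), "at least 3")
    expect_error(additiveCnModel(rep(1, 10), rnorm(10)), "constant")
})

test_that("group contrasts separate additive from saturating regimes", {
    strains <- sprintf("s%d", 1:20)
    copies <- rep(c(1, 2), each = 10)
    ## saturating, noiseless: no difference between 1 and 2 copies
    sat <- simulatePhenotypes(data.frame(strain = strains,
                                         copies = copies),
                              slope = 1, saturating = TRUE, noiseSD = 0)
    gc1 <- groupContrast(sat$copies, sat$phenotype)
    expect_equal(gc1$difference, 0)
    expect_gte(gc1$p, 0.9)
    ## saturating mode still separates 0 from 1 copy
    sat0 <- simulatePhenotypes(
        data.frame(strain = strains, copies = rep(c(0, 1), each = 10)),
        slope = 1, saturating = TRUE, noiseSD = 0)
    expect_equal(groupContrast(sat0$copies, sat0$phenotype,
                               groups = c(1, 0))$difference, 1)
    ## additive with modest noise: difference near the slope, usually
    ## significant
    hits <- vapply(1:20, function(s) {
        ph <- simulatePhenotypes(data.frame(strain = strains,
                                            copies = copies),
                                 slope = 1, noiseSD = 0.1,
                                 seed = 700 + s)
        gc <- groupContrast(ph$copies, ph$phenotype, groups = c(2, 1))
        abs(gc$difference - 1) < 0.3 && gc$p < 0.01
    }, TRUE)
    expect_gte(sum(hits), 18L)
})

test_that("phenotype generator residual noise is calibrated", {
    sds <- vapply(1:10, function(s) {
        ph <- simulatePhenotypes(
            data.frame(strain = sprintf("s%d", 1:60),
                       copies = sample(0:3, 60, replace = TRUE)),
            slope = 1, noiseSD = 0.5, seed = 800 + s)
        fit <- lm(phenotype ~ copies, ph)
        summary(fit)$sigma
    }, 0)
    expect_true(all(abs(sds - 0.5) / 0.5 < 0.3))
})

test_that("CNV profile distances cluster strains by profile", {
    win <- seq(1, 49501, by = 500)
    mk <- function(depth, strain) windowedLog2Depth(
        data.frame(chrom = "c", start = win, end = win + 499,
                   depth = depth), strain = strain)
    base <- rep(30, length(win))
    amp <- base; amp[20:40] <- 60
    tracks <- list(a = mk(base, "a"), b = mk(base, "b"),
                   c = mk(amp, "c"))
    d <- cnvProfileDistance(tracks)
    expect_equal(d["a", "b"], 0)
    expect_gt(d["a", "c"], 1)
})
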