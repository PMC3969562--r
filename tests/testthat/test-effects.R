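test_that("indel genotype threshold rule is strict at 5.3", {
    expect_identical(callIndelGenotype(c(6, -6, 2, 5.3, -5.3)),
                     c("alt", "ref", NA, NA, NA))
})

test_that("SNP effects match hand-built codon cases on both strands", {
    g <- .handGenome()
    ## plus-strand ORF at 11: ATG GAA GAT TGC TAA
    ## GAA -> TAA at codon 2 position 1 (genomic 14): stop gain
    expect_identical(classifySnpEffect(
        data.frame(chrom = "chrT", pos = 14, ref = "G", alt = "T"), g),
        "stop_gain")
    ## GAA -> GAG (third position, genomic 16): synonymous
    expect_identical(classifySnpEffect(
        data.frame(chrom = "chrT", pos = 16, ref = "A", alt = "G"), g),
        "synonymous")
    ## GAT -> CAT (genomic 17): nonsynonymous
    expect_identical(classifySnpEffect(
        data.frame(chrom = "chrT", pos = 17, ref = "G", alt = "C"), g),
        "nonsynonymous")
    ## TAA -> CAA at the stop codon (genomic 23): stop loss
    expect_identical(classifySnpEffect(
        data.frame(chrom = "chrT", pos = 23, ref = "T", alt = "C"), g),
        "stop_loss")
    ## outside any ORF
    expect_identical(classifySnpEffect(
        data.frame(chrom = "chrT", pos = 5, ref = "C", alt = "A"), g),
        "intergenic")
    ## minus-strand ORF at 41-55 mirrors the plus-strand codons:
    ## genomic position 52 is codon-2 position-1 on the minus strand
    expect_identical(classifySnpEffect(
        data.frame(chrom = "chrT", pos = 52, ref = "C", alt = "A"), g),
        "stop_gain")
})

test_that("effect classification agrees with whole-ORF retranslation", {
    g <- .fixtureGenome()
    orfs <- orfAnnotation(g)
    seqs <- genomeSequences(g)
    set.seed(41)
    checked <- 0L
    while (checked < 300L) {
        o <- orfs[sample(length(orfs), 1L)]
        pos <- sample(start(o):end(o), 1L)
        chrom <- as.character(seqnames(o))
        refb <- as.character(Biostrings::subseq(seqs[[chrom]], pos, pos))
        alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
        ## skip positions inside overlapping ORF pairs: the single-effect
        ## wrapper reports the most severe across ORFs
        if (sum(as.character(seqnames(orfs)) == chrom &
                start(orfs) <= pos & end(orfs) >= pos) != 1L) next
        got <- classifySnpEffect(
            data.frame(chrom = chrom, pos = pos, ref = refb, alt = alt), g)
        want <- translationEffectOracle(g, chrom, pos, alt, o)
        expect_identical(got, want)
        checked <- checked + 1L
    }
})

test_that("equivalent indel regions match exhaustive enumeration", {
    cases <- list(
        ## insertion of A into an A-run: run plus insertion point
        list(seq = "GGCAAAATCG", pos = 4L, ref = "", alt = "A"),
        ## non-repetitive insertion: single anchor
        list(seq = "GACTGACT", pos = 4L, ref = "", alt = "TT"),
        ## CT insertion in a (CT)3 microsatellite
        list(seq = "GGACTCTCTAGG", pos = 4L, ref = "", alt = "CT"),
        ## deletion of one A from a run: the whole run
        list(seq = "GGCAAAATCG", pos = 3L, ref = "A", alt = ""),
        ## deletion in unique context
        list(seq = "GACTGTCA", pos = 3L, ref = "TG", alt = ""),
        ## VCF-style anchored representation
        list(seq = "GGCAAAATCG", pos = 3L, ref = "CA", alt = "C"))
    for (cs in cases) {
        got <- equivalentIndelRegion(cs$seq, cs$pos, cs$ref, cs$alt)
        want <- equivalentRegionOracle(cs$seq, cs$pos, cs$ref, cs$alt)
        ## oracle takes the stripped representation
        if (nchar(cs$ref) && nchar(cs$alt)) {
            st <- popcontent:::.stripIndel(cs$pos, cs$ref, cs$alt)
            want <- equivalentRegionOracle(cs$seq, st$pos, st$ref, st$alt)
        }
        expect_identical(got, want)
    }
    ## randomized property: agreement on homopolymer-rich sequences
    set.seed(42)
    for (i in 1:150) {
        s <- paste(sample(c("A", "C"), 30, replace = TRUE,
                          prob = c(0.7, 0.3)), collapse = "")
        if (runif(1) < 0.5) {
            pos <- sample(5:20, 1L)
            alt <- paste(sample(c("A", "C"),
                                sample(1:3, 1L), replace = TRUE),
                         collapse = "")
            got <- equivalentIndelRegion(s, pos, "", alt)
            want <- equivalentRegionOracle(s, pos, "", alt)
        } else {
            pos <- sample(5:18, 1L)
            k <- sample(1:3, 1L)
            ref <- substr(s, pos + 1, pos + k)
            got <- equivalentIndelRegion(s, pos, ref, "")
            want <- equivalentRegionOracle(s, pos, ref, "")
        }
        expect_identical(got, want)
    }
})

test_that("indel ORF effects require contained equivalent regions", {
    g <- .handGenome()
    orfP <- orfAnnotation(g)[1L]
    ## 2-bp insertion mid-ORF: frameshift
    expect_identical(
        classifyIndelOrfEffect(g, "chrT", 18L, "", "GG", orfP),
        "frameshift")
    ## 3-bp deletion inside the ORF: in-frame
    expect_identical(
        classifyIndelOrfEffect(g, "chrT", 14L, "AGA", "", orfP),
        "in_frame")
    ## insertion of A right after the ORF's initial A: an equivalent
    ## placement exists before the ORF start, so the region crosses the
    ## boundary and the indel does not count as affecting the ORF
    expect_identical(
        classifyIndelOrfEffect(g, "chrT", 11L, "", "A", orfP),
        "not_in_orf")
})

test_that("LoF calling applies dubious and 3'-tail exclusions", {
    ## genome with one verified and one dubious ORF; codons 50 and 99
    ## are CAA so a C->T substitution creates a premature TAA stop
    set.seed(43)
    codons <- sample(setdiff(popcontent:::.SENSE_CODONS,
                             c("CAA", "TAA", "TAG", "TGA")),
                     98, replace = TRUE)
    codons[c(49, 98)] <- "CAA"             # codons 50 and 99 of the ORF
    orfSeq <- paste0("ATG", paste(codons, collapse = ""), "TAA")  # 300 bp
    seqChr <- paste0(strrep("C", 50), orfSeq, strrep("C", 50),
                     orfSeq, strrep("C", 50))
    seqs <- Biostrings::DNAStringSet(seqChr); names(seqs) <- "chrZ"
    orfs <- GRanges("chrZ", IRanges(c(51, 401), width = 300),
                    strand = "+",
                    orf_id = c("GOOD", "DUBI"),
                    class = c("verified", "dubious"),
                    essential = FALSE)
    g <- new("AnnotatedGenome", sequences = seqs, orfs = orfs,
             repeats = GRanges(), subtelomereSpan = 10L)
    ## premature stops: codon 50 (rel 0.49) and codon 99 (rel 0.98,
    ## inside the excluded last 2%); same substitution in the dubious ORF
    stopAt <- function(orfStart, codonIdx) orfStart + 3L * (codonIdx - 1L)
    vars <- data.frame(
        variant_id = c("v_mid", "v_tail", "v_dub", "v_fs"),
        type = c("snp", "snp", "snp", "ins"),
        chrom = "chrZ",
        pos = c(stopAt(51, 50), stopAt(51, 99), stopAt(401, 50),
                51 + 150),
        ref = c("C", "C", "C", ""),
        alt = c("T", "T", "T", "TT"))
    carriers <- matrix(TRUE, 4, 2,
                       dimnames = list(vars$variant_id, c("sA", "sB")))
    out <- callLof(vars, carriers, g)
    expect_setequal(unique(out$calls$variant_id), c("v_mid", "v_fs"))
    expect_setequal(out$calls$kind[out$calls$variant_id == "v_fs"],
                    "frameshift")
    ## per-gene summary counts affected strains
    expect_equal(out$perGene$n_strains[out$perGene$orf_id == "GOOD"], 2L)
    ## with dubious ORFs included, the dubious-ORF stop is called
    out2 <- callLof(vars, carriers, g, excludeDubious = FALSE)
    expect_true("v_dub" %in% out2$calls$variant_id)
})

test_that("planted LoF events are recovered with full recall and no extras", {
    g <- .fixtureGenome()
    pop <- simulatePopulation(g, starTree(4, 1.5e-3),
                              rates = list(snp = 1, indel = 0.05,
                                           gain = 0, loss = 0, cnv = 0,
                                           lof = 6e-3),
                              frameshiftRejection = 1, seed = 44)
    ev <- pop$truth$events
    vars <- data.frame(variant_id = ev$event_id, type = ev$type,
                       chrom = ev$chrom, pos = ev$start, ref = ev$ref,
                       alt = ev$alt)
    keep <- vars$type %in% c("snp", "ins", "del")
    out <- callLof(vars[keep, ], pop$truth$carriers[keep, ], g)
    truthIds <- ev$event_id[ev$lof]
    expect_gt(length(truthIds), 2)
    expect_true(all(truthIds %in% out$calls$variant_id))
    expect_true(all(out$calls$variant_id %in% truthIds))
})

test_that("positional enrichment reproduces exact binomial arithmetic", {
    set.seed(45)
    u <- runif(400)
    nul <- positionalEnrichment(u)
    expect_lt(abs(nul$fold - 1), 0.6)
    rel <- c(runif(80), runif(20, 0.95, 1))
    pe <- positionalEnrichment(rel, 0.05)
    k <- sum(rel >= 0.95)
    expect_equal(pe$fold, (k / 100) / 0.05)
    expect_equal(pe$p, binomTailOracle(k, 100, 0.05), tolerance = 1e-12)
    ## the worked 20-of-100 example
    relFixed <- c(rep(0.5, 80), rep(0.99, 20))
    pf <- positionalEnrichment(relFixed, 0.05)
    expect_equal(pf$fold, 4.0)
    expect_equal(pf$p, binomTailOracle(20, 100, 0.05), tolerance = 1e-12)
    expect_equal(positionalEnrichment(rep(0.5, 50), 0.05)$fold, 0)
})

test_that("frame-preservation table gives the sample odds ratio and exact p", {
    lengths <- c(rep(3, 30), rep(4, 10), rep(6, 20), rep(5, 40))
    inOrf <- c(rep(TRUE, 40), rep(FALSE, 60))
    fp <- framePreservationSpectrum(lengths, inOrf)
    expect_equal(unname(fp$table), matrix(c(30, 10, 20, 40), 2,
                                          byrow = TRUE))
    expect_equal(fp$oddsRatio, 6.0)
    expect_equal(fp$p, fisherEnumOracle(fp$table), tolerance = 1e-10)
})

test_that("selection against frameshifts shows as mod-3 enrichment in ORFs", {
    ors <- vapply(1:5, function(s) {
        g <- .fixtureGenome()
        pop <- simulatePopulation(g, starTree(2, 4e-3),
                                  rates = list(snp = 0, indel = 0.3,
                                               gain = 0, loss = 0,
                                               cnv = 0, lof = 0),
                                  frameshiftRejection = 0.9,
                                  seed = 500 + s)
        ev <- pop$truth$events
        ind <- ev[ev$type %in% c("ins", "del"), ]
        orfs <- orfAnnotation(g)
        inOrf <- vapply(seq_len(nrow(ind)), function(i) {
            any(as.character(seqnames(orfs)) == ind$chrom[i] &
                start(orfs) <= ind$start[i] & end(orfs) >= ind$end[i])
        }, TRUE)
        framePreservationSpectrum(ind$length, inOrf)$oddsRatio
    }, 0)
    expect_true(all(ors > 1))
    expect_gt(mean(ors), 3)
})

test_that("Fisher p-values match hypergeometric enumeration on random tables", {
    set.seed(46)
    for (i in 1:60) {
        tab <- matrix(sample(0:50, 4, replace = TRUE), 2)
        if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
        p <- stats::fisher.test(tab)$p.value
        expect_equal(p, fisherEnumOracle(tab), tolerance = 1e-10)
    }
})

test_that("polarization follows the outgroup-match rule", {
    vars <- data.frame(variant_id = c("v1", "v2", "v3"),
                       ref = c("A", "G", "T"), alt = c("G", "A", "A"))
    carriers <- rbind(v1 = c(rep(FALSE, 17), TRUE),
                      v2 = rep(TRUE, 18),
                      v3 = c(rep(TRUE, 9), rep(FALSE, 9)))
    colnames(carriers) <- sprintf("s%02d", 1:18)
    pol <- polarizeAlleles(vars, carriers, outgroup = c("A", "A", "C"))
    ## v1: outgroup matches ref; single derived G
    expect_equal(pol$derived_count[1L], 1L)
    expect_identical(pol$derived[1L], "G")
    ## v2: outgroup matches alt; derived is ref, carried by nobody -> 0
    expect_identical(pol$ancestral[2L], "A")
    expect_equal(pol$derived_count[2L], 0L)
    ## v3: outgroup allele matches neither -> unpolarized
    expect_false(pol$polarized[3L])
    ## spectrum mass conservation: polarized segregating variants only
    spec <- dafSpectrum(pol, c("nonsynonymous", "synonymous",
                               "synonymous"))
    expect_equal(sum(spec),
                 sum(pol$polarized & pol$derived_count >= 1, na.rm = TRUE))
    expect_equal(unname(spec["1", "nonsynonymous"]), 1L)
})

test_that("singleton fraction rises with purifying-selection strength", {
    ## deleterious derived alleles are held at low frequency: emulate
    ## selection by thinning high-frequency deleterious variants
    set.seed(47)
    n <- 18L
    mkSpec <- function(strength) {
        freq <- sample.int(n, 600, replace = TRUE,
                           prob = (1 / (1:n)))
        keep <- runif(600) < exp(-strength * (freq - 1) / n)
        tab <- tabulate(freq[keep], n)
        tab[1L] / sum(tab)
    }
    s <- vapply(c(0, 2, 6), mkSpec, 0)
    expect_true(all(diff(s) > 0))
})

test_that("pooled pN/pS ratios and Fisher comparison match the worked case", {
    snps <- data.frame(
        orf_id = c(rep("gA", 1643), rep("gB", 1485)),
        effect = c(rep("nonsynonymous", 643), rep("synonymous", 1000),
                   rep("nonsynonymous", 485), rep("synonymous", 1000)))
    out <- pnPs(snps, "gA", "gB")
    expect_equal(out$setA$ratio, 0.643, tolerance = 1e-12)
    expect_equal(out$setB$ratio, 0.485, tolerance = 1e-12)
    tab <- matrix(c(643, 1000, 485, 1000), 2)
    expect_equal(out$p, stats::fisher.test(tab)$p.value, tolerance = 1e-12)
    ## identical sets give p = 1
    expect_equal(pnPs(snps, "gA", "gA")$p, 1)
})

test_that("relaxed selection on one gene set raises its pN/pS", {
    set.seed(48)
    wins <- vapply(1:10, function(s) {
        ## set A retains nonsynonymous variants at twice the rate of B
        nA <- rbinom(1, 400, 0.4); nB <- rbinom(1, 400, 0.2)
        snps <- data.frame(
            orf_id = c(rep("gA", nA + 300), rep("gB", nB + 300)),
            effect = c(rep("nonsynonymous", nA), rep("synonymous", 300),
                       rep("nonsynonymous", nB), rep("synonymous", 300)))
        out <- pnPs(snps, "gA", "gB")
        out$setA$ratio > out$setB$ratio
    }, TRUE)
    expect_gte(sum(wins), 9L)
})

test_that("paralog counting applies significance and coverage rules", {
    hits <- data.frame(
        query = c("g1", "g1", "g2"),
        subject = c("g2", "g3", "g1"),
        significant = c(TRUE, TRUE, TRUE),
        coverage = c(0.9, 0.6, 0.85))
    counts <- countParalogs(hits, c("g1", "g2", "g3"))
    expect_equal(unname(counts), c(1L, 1L, 0L))
    ## planted identical 4-copy family via the built-in protein engine
    set.seed(49)
    fam <- paste(sample(Biostrings::AA_STANDARD, 120, replace = TRUE),
                 collapse = "")
    unique1 <- paste(sample(Biostrings::AA_STANDARD, 150, replace = TRUE),
                     collapse = "")
    prot <- Biostrings::AAStringSet(c(f1 = fam, f2 = fam, f3 = fam,
                                      f4 = fam, u1 = unique1))
    ph <- proteinSimilarityHits(prot)
    pc <- countParalogs(ph, names(prot))
    expect_equal(unname(pc[c("f1", "f2", "f3", "f4")]), rep(3L, 4))
    expect_equal(unname(pc["u1"]), 0L)
})
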