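cand <- function(query, start, end, score, is_top, sl, sr,
                 edge = FALSE, scaffold = "scf1", strand = "+",
                 similarity = 0.95) {
    data.frame(query = query, scaffold = scaffold, start = start,
               end = end, strand = strand, similarity = similarity,
               score = score, is_top = is_top, synteny_left = sl,
               synteny_right = sr, at_edge = edge)
}

test_that("priority tiers select candidates in the documented order", {
    ## tier 1: top score with synteny both sides
    c1 <- rbind(cand("g1", 100, 1000, 900, TRUE, TRUE, TRUE),
                cand("g1", 5000, 5900, 880, TRUE, FALSE, FALSE))
    a1 <- assignHomologs(c1)
    expect_equal(a1$tier, 1L)
    expect_equal(a1$start, 100)
    ## tier 3 beats an unsupported top candidate
    c3 <- rbind(cand("g2", 100, 1000, 1000, TRUE, FALSE, FALSE),
                cand("g2", 5000, 5900, 920, FALSE, TRUE, TRUE))
    a3 <- assignHomologs(c3)
    expect_equal(a3$tier, 3L)
    expect_equal(a3$start, 5000)
    ## tier 2: one-sided synteny at a scaffold edge
    c2 <- rbind(cand("g3", 100, 1000, 1000, TRUE, TRUE, FALSE,
                     edge = TRUE),
                cand("g3", 5000, 5900, 950, FALSE, FALSE, FALSE))
    a2 <- assignHomologs(c2)
    expect_equal(a2$tier, 2L)
    ## no support anywhere: unassigned
    c0 <- cand("g4", 100, 1000, 1000, TRUE, FALSE, FALSE)
    expect_equal(nrow(assignHomologs(c0)), 0L)
})

test_that("assignment is invariant under candidate row order", {
    cc <- rbind(cand("g1", 100, 1000, 900, TRUE, TRUE, TRUE),
                cand("g1", 5000, 5900, 895, TRUE, TRUE, TRUE),
                cand("g2", 7000, 7800, 700, TRUE, TRUE, TRUE))
    a <- assignHomologs(cc)
    b <- assignHomologs(cc[c(3, 1, 2), ])
    rownames(a) <- rownames(b) <- NULL
    expect_identical(a, b)
})

test_that("deduplication keeps one assignment per locus by priority", {
    ## far apart: both kept
    far <- rbind(cbind(cand("g1", 100, 1000, 900, TRUE, TRUE, TRUE),
                       tier = 1L),
                 cbind(cand("g2", 4000, 4900, 800, TRUE, TRUE, TRUE),
                       tier = 1L))
    expect_equal(nrow(deduplicateAssignments(far)), 2L)
    ## same locus (starts 40 bp, ends 60 bp apart): tier 1 wins
    near <- rbind(cbind(cand("g1", 100, 1000, 900, TRUE, TRUE, TRUE),
                        tier = 1L),
                  cbind(cand("g2", 140, 1060, 950, FALSE, TRUE, TRUE),
                        tier = 3L))
    d <- deduplicateAssignments(near)
    expect_equal(d$query, "g1")
    expect_equal(attr(d, "dropped")$rule, "lower_priority_tier")
    ## equal tier and score: longer gene wins
    eq <- rbind(cbind(cand("g1", 100, 1000, 900, TRUE, TRUE, TRUE),
                      tier = 1L),
                cbind(cand("g2", 130, 1029, 900, TRUE, TRUE, TRUE),
                      tier = 1L))
    d2 <- deduplicateAssignments(eq)
    expect_equal(d2$query, "g1")  # 901 bp beats 900 bp
    expect_lte(nrow(d2), nrow(eq))
})

test_that("nonreference classification applies length and similarity rules", {
    set.seed(61)
    rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")
    refGenes <- Biostrings::DNAStringSet(c(r1 = rnd(900), r2 = rnd(600)))
    ## pred1: novel 500 bp; pred2: 250 bp (too short);
    ## pred3: contains a 210-bp exact copy of a reference gene segment
    novel <- rnd(500)
    short <- rnd(250)
    withHit <- paste0(rnd(150), substr(as.character(refGenes[["r1"]]),
                                       100, 309), rnd(140))
    predSeqs <- Biostrings::DNAStringSet(c(p1 = novel, p2 = short,
                                           p3 = withHit))
    pred <- GRanges(rep("scf1", 3),
                    IRanges(c(1000, 3000, 5000),
                            width = c(500, 250, 500)))
    names(pred) <- names(predSeqs)
    out <- classifyNonreferenceGenes(pred, predSeqs, refGenes,
                                     assigned = GRanges())
    expect_identical(out, "p1")
    ## overlap with an assigned homolog interval disqualifies
    out2 <- classifyNonreferenceGenes(pred, predSeqs, refGenes,
                                      assigned = GRanges("scf1",
                                                         IRanges(900, 1100)))
    expect_length(out2, 0L)
})

test_that("planted homologs and a novel gene are recovered end to end", {
    g <- simulateReferenceGenome(1, 1.5e5, subtelomereSpan = 33000,
                                 orfDensity = 1 / 3000, seed = 62)
    pop <- simulatePopulation(g, starTree(2, 1e-3),
                              rates = list(snp = 1, indel = 0, gain = 0,
                                           loss = 0, cnv = 0, lof = 0),
                              seed = 63)
    assembly <- pop$genomes$s1
    names(assembly) <- "scf1"
    candidates <- homologCandidates(g, assembly)
    candidates <- syntenyFlags(candidates, g,
                               scaffoldLengths = c(scf1 = width(assembly)))
    asg <- deduplicateAssignments(assignHomologs(candidates))
    orfs <- orfAnnotation(g)
    expected <- mcols(orfs)$orf_id[mcols(orfs)$class != "dubious"]
    recall <- mean(expected %in% asg$query)
    expect_gte(recall, 0.95)
    ## placements should coincide with truth coordinates (no structural
    ## edits were simulated, so positions are preserved)
    rownames(asg) <- asg$query
    hit <- expected[expected %in% asg$query]
    tr <- orfs[match(hit, mcols(orfs)$orf_id)]
    dev <- abs(asg[hit, "start"] - start(tr)) +
        abs(asg[hit, "end"] - end(tr))
    expect_gte(mean(dev <= 60), 0.95)

    ## a planted novel gene is classified nonreference
    set.seed(64)
    novelGene <- paste(sample(c("A", "C", "G", "T"), 600,
                              replace = TRUE), collapse = "")
    asm2 <- Biostrings::DNAStringSet(
        paste0(substr(as.character(assembly[[1L]]), 1, 70000), novelGene,
               substr(as.character(assembly[[1L]]), 70001,
                      width(assembly))))
    names(asm2) <- "scf1"
    refSeqs <- DNAStringSet(lapply(seq_along(orfs), function(i) {
        o <- orfs[i]
        s <- Biostrings::subseq(
            genomeSequences(g)[[as.character(seqnames(o))]],
            start(o), end(o))
        if (as.character(strand(o)) == "-")
            s <- Biostrings::reverseComplement(s)
        s
    }))
    names(refSeqs) <- mcols(orfs)$orf_id
    predicted <- GRanges("scf1", IRanges(70001, 70600))
    names(predicted) <- "novel1"
    predSeqs <- Biostrings::DNAStringSet(c(novel1 = novelGene))
    assigned <- GRanges(asg$scaffold, IRanges(asg$start, asg$end))
    nov <- classifyNonreferenceGenes(predicted, predSeqs, refSeqs,
                                     assigned)
    expect_identical(nov, "novel1")
})

test_that("the naive ORF finder honors the length floor and strands", {
    g <- .handGenome()
    ## hand genome ORFs are 15 bp; with minLength 15 both strands found
    orfs <- findOrfsNaive(genomeSequences(g), minLength = 15L)
    expect_gte(length(orfs), 2L)
    expect_true(all(width(orfs) %% 3L == 0L))
    expect_length(findOrfsNaive(genomeSequences(g), minLength = 300L), 0L)
})
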