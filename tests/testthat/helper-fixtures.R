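## Shared fixtures, built once per test run.

## A small annotated genome used by several files.
.fixtureGenome <- local({
    val <- NULL
    function() {
        if (is.null(val))
            val <<- simulateReferenceGenome(2, 1e5, subtelomereSpan = 20000,
                                            seed = 101)
        val
    }
})

## A tiny genome with a single hand-built ORF for codon arithmetic tests:
## chr sequence has ORF "ATG GAA GAT TGC TAA" planted at position 11 on
## the plus strand, and the same ORF reverse-complemented at position 41.
.handGenome <- function() {
    orfSeq <- "ATGGAAGATTGCTAA"
    pad1 <- "CCCCCCCCCC"                     # 1..10
    rcOrf <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(orfSeq)))
    mid <- "CCCCCCCCCCCCCCC"                 # 26..40
    tail <- "CCCCCCCCCC"                     # 56..65
    seqs <- Biostrings::DNAStringSet(
        paste0(pad1, orfSeq, mid, rcOrf, tail))
    names(seqs) <- "chrT"
    orfs <- GenomicRanges::GRanges(
        "chrT", IRanges::IRanges(c(11L, 41L), c(25L, 55L)),
        strand = c("+", "-"),
        orf_id = c("ORFP", "ORFM"),
        class = c("verified", "verified"),
        essential = c(FALSE, FALSE))
    new("AnnotatedGenome", sequences = seqs, orfs = orfs,
        repeats = GenomicRanges::GRanges(), subtelomereSpan = 10L)
}

## Run the full linkage-scaffolding pipeline on a simulated instance and
## score it against truth. Returns the recovery stats plus intermediates.
runScaffoldRecovery <- function(seed, nChrom = 2L, chromLen = 1e6L,
                                n50 = 1e5L, minScaffold = 2e4L,
                                nSegregants = 170L, nContaminants = 20L,
                                branchLen = 2e-4, genotypingError = 0.002,
                                design = NULL) {
    g <- simulateReferenceGenome(nChrom, chromLen, orfDensity = 0,
                                 repeatDensity = 0, seed = seed)
    pop <- simulatePopulation(g, starTree(2, branchLen),
                              rates = list(snp = 1, indel = 0, gain = 0,
                                           loss = 0, cnv = 0, lof = 0),
                              seed = seed + 1000L)
    m <- crossMarkers(pop$truth, c("s1", "s2"))
    frag <- fragmentGenome(genomeSequences(g), n50, minScaffold,
                           seed = seed + 2000L)
    chromLens <- stats::setNames(width(genomeSequences(g)),
                                 names(genomeSequences(g)))
    if (is.null(design))
        design <- crossDesign(nSegregants = nSegregants,
                              nContaminants = nContaminants,
                              genotypingError = genotypingError)
    cr <- simulateIntercross(m, chromLens, design, seed = seed + 3000L)
    llr <- remapLlrTable(cr$llr, frag$placement)
    gm <- filterSegregants(callSegregantGenotypes(llr))$genotypes
    ldw <- computePairwiseLD(gm, "within")
    scfLens <- stats::setNames(as.numeric(width(frag$scaffolds)),
                               names(frag$scaffolds))
    fit <- fitLdDecay(ldw, scfLens)
    graph <- buildScaffoldLinks(gm, model = fit,
                                scaffoldLengths = scfLens)
    traced <- traceLinkageGroups(graph)
    stats <- scaffoldRecoveryStats(traced, frag$placement)
    list(stats = stats, graph = traced, fit = fit, pairs = ldw,
         genotypes = gm, placement = frag$placement, cross = cr,
         markers = m, genome = g)
}
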