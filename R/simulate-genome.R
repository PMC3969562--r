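#' Simulate an annotated reference-like genome
#'
#' Generates a random genome with planted ORFs (start codon, sense-codon
#' body, stop codon; length a multiple of 3; both strands), repeat
#' intervals built from a shared transposon-like consensus, and subtelomere
#' annotation (outermost \code{subtelomereSpan} bp of each chromosome).
#' Deterministic for a fixed seed.
#'
#' @param nChromosomes Number of chromosomes.
#' @param chromosomeLengths Integer vector (recycled) of chromosome lengths
#'   in bp; each must be at least \code{2 * subtelomereSpan}.
#' @param orfDensity Expected ORFs per bp (default 1 per 2 kb).
#' @param dubiousFraction Fraction of ORFs labelled \code{"dubious"}.
#' @param uncharacterizedFraction Fraction labelled
#'   \code{"uncharacterized"}; the rest are \code{"verified"}.
#' @param essentialFraction Fraction of non-dubious ORFs flagged essential.
#' @param repeatDensity Expected repeat instances per bp.
#' @param subtelomereSpan Subtelomere span per chromosome end in bp.
#' @param seed Integer seed (RNG state is restored on exit).
#' @return An \linkS4class{AnnotatedGenome}.
#' @examples
#' g <- simulateReferenceGenome(2, 1e5, subtelomereSpan = 20000, seed = 1)
#' g
#' @export
simulateReferenceGenome <- function(nChromosomes = 2L,
                                    chromosomeLengths = 200000L,
                                    orfDensity = 1 / 2000,
                                    dubiousFraction = 0.10,
                                    uncharacterizedFraction = 0.20,
                                    essentialFraction = 0.20,
                                    repeatDensity = 1 / 50000,
                                    subtelomereSpan = 33000L,
                                    seed = NULL) {
    lens <- as.integer(rep_len(chromosomeLengths, nChromosomes))
    if (any(lens < 2L * subtelomereSpan))
        .stopf("chromosome length must be >= 2 x subtelomereSpan (%d bp)",
               2L * subtelomereSpan)
    .withSeed(seed, {
        chromNames <- sprintf("chr%02d", seq_len(nChromosomes))
        seqChars <- lapply(lens, .randomDnaVector)
        names(seqChars) <- chromNames
        repeatConsensus <- .randomDnaVector(5000L)

        orfRows <- list(); repRows <- list()
        for (i in seq_len(nChromosomes)) {
            L <- lens[i]
            ## --- repeats: copies of a shared consensus prefix
            nRep <- stats::rpois(1L, repeatDensity * L)
            occupied <- integer(0)
            if (nRep > 0L) {
                for (k in seq_len(nRep)) {
                    w <- sample(300:5000, 1L)
                    s <- .placeInterval(L, w, occupied, tries = 30L)
                    if (is.na(s)) next
                    occupied <- c(occupied, s:(s + w - 1L))
                    seqChars[[i]][s:(s + w - 1L)] <- repeatConsensus[seq_len(w)]
                    repRows[[length(repRows) + 1L]] <-
                        data.frame(chrom = chromNames[i], start = s,
                                   end = s + w - 1L)
                }
            }
            ## --- ORFs: non-overlapping, random strand
            nOrf <- stats::rpois(1L, orfDensity * L)
            for (k in seq_len(nOrf)) {
                nCodon <- sample(100:500, 1L)  # 300-1500 bp
                w <- 3L * nCodon
                s <- .placeInterval(L, w, occupied, tries = 30L)
                if (is.na(s)) next
                occupied <- c(occupied, s:(s + w - 1L))
                strand <- sample(c("+", "-"), 1L)
                body <- sample(.SENSE_CODONS, nCodon - 2L, replace = TRUE)
                orfSeq <- paste0("ATG", paste(body, collapse = ""), "TAA")
                if (strand == "-") orfSeq <- .revcompChar(orfSeq)
                seqChars[[i]][s:(s + w - 1L)] <-
                    strsplit(orfSeq, "", fixed = TRUE)[[1L]]
                orfRows[[length(orfRows) + 1L]] <-
                    data.frame(chrom = chromNames[i], start = s,
                               end = s + w - 1L, strand = strand)
            }
        }
        orfDf <- if (length(orfRows)) do.call(rbind, orfRows) else
            data.frame(chrom = character(), start = integer(),
                       end = integer(), strand = character())
        repDf <- if (length(repRows)) do.call(rbind, repRows) else
            data.frame(chrom = character(), start = integer(),
                       end = integer())
        orfDf <- orfDf[order(orfDf$chrom, orfDf$start), , drop = FALSE]
        nOrfTot <- nrow(orfDf)
        cls <- rep("verified", nOrfTot)
        if (nOrfTot) {
            u <- stats::runif(nOrfTot)
            cls[u < dubiousFraction + uncharacterizedFraction] <- "uncharacterized"
            cls[u < dubiousFraction] <- "dubious"
        }
        essential <- cls != "dubious" & stats::runif(nOrfTot) < essentialFraction

        seqs <- DNAStringSet(vapply(seqChars, paste, "", collapse = ""))
        orfs <- GRanges(orfDf$chrom,
                        IRanges(orfDf$start, orfDf$end),
                        strand = orfDf$strand,
                        orf_id = sprintf("ORF%04d", seq_len(nOrfTot)),
                        class = cls, essential = essential)
        reps <- GRanges(repDf$chrom, IRanges(repDf$start, repDf$end))
        new("AnnotatedGenome", sequences = seqs, orfs = orfs, repeats = reps,
            subtelomereSpan = as.integer(subtelomereSpan))
    })
}

## Sample a start for an interval of width w in [1, L] avoiding occupied
## positions; NA if no luck after `tries` draws.
.placeInterval <- function(L, w, occupied, tries = 30L) {
    if (w > L) return(NA_integer_)
    for (t in seq_len(tries)) {
        s <- sample.int(L - w + 1L, 1L)
        if (!length(occupied) || !any((s:(s + w - 1L)) %in% occupied))
            return(s)
    }
    NA_integer_
}

#' Export genome sequences and annotation
#'
#' Writes the genome FASTA via \code{Biostrings::writeXStringSet} and the
#' ORF/repeat annotation as GFF3 via \pkg{rtracklayer}. Subtelomeres can be
#' written as BED.
#'
#' @param genome An \code{AnnotatedGenome}.
#' @param fastaFile,gffFile,subtelomereBed Output paths (NULL to skip).
#' @return Invisibly, the vector of files written.
#' @export
exportGenome <- function(genome, fastaFile = NULL, gffFile = NULL,
                         subtelomereBed = NULL) {
    written <- character()
    if (!is.null(fastaFile)) {
        Biostrings::writeXStringSet(genomeSequences(genome), fastaFile)
        written <- c(written, fastaFile)
    }
    if (!is.null(gffFile)) {
        if (!requireNamespace("rtracklayer", quietly = TRUE))
            .stopf("rtracklayer is required for GFF3 export")
        orfs <- orfAnnotation(genome)
        if (length(orfs)) {
            mcols(orfs)$type <- "gene"
            mcols(orfs)$ID <- mcols(orfs)$orf_id
        }
        reps <- repeatAnnotation(genome)
        if (length(reps)) mcols(reps)$type <- "repeat_region"
        rtracklayer::export(c(GRanges(orfs), GRanges(reps)), gffFile,
                            format = "gff3")
        written <- c(written, gffFile)
    }
    if (!is.null(subtelomereBed)) {
        st <- subtelomeres(genome)
        df <- data.frame(chrom = as.character(seqnames(st)),
                         start = start(st) - 1L, end = end(st))
        utils::write.table(df, subtelomereBed, sep = "\t",
                           quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
        written <- c(written, subtelomereBed)
    }
    invisible(written)
}
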