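#' Classify the coding effect of a SNP
#'
#' Strand-aware codon arithmetic on the annotated ORF using the standard
#' nuclear genetic code. Positions outside every ORF are intergenic. When
#' a SNP falls in several overlapping ORFs it is evaluated independently
#' against each and the most severe effect is reported
#' (stop_gain > stop_loss > nonsynonymous > synonymous).
#'
#' @param snps data.frame \code{chrom}, \code{pos}, \code{ref}, \code{alt}.
#' @param genome An \linkS4class{AnnotatedGenome}.
#' @return Character vector of effects in \{"intergenic", "synonymous",
#'   "nonsynonymous", "stop_gain", "stop_loss"\}.
#' @export
classifySnpEffect <- function(snps, genome) {
    orfs <- orfAnnotation(genome)
    seqs <- genomeSequences(genome)
    chars <- lapply(as.character(seqs), function(s)
        strsplit(s, "", fixed = TRUE)[[1L]])
    severity <- c(stop_gain = 4L, stop_loss = 3L, nonsynonymous = 2L,
                  synonymous = 1L)
    gc <- Biostrings::GENETIC_CODE
    vapply(seq_len(nrow(snps)), function(i) {
        chrom <- snps$chrom[i]; pos <- snps$pos[i]; alt <- snps$alt[i]
        hits <- which(as.character(seqnames(orfs)) == chrom &
                      start(orfs) <= pos & end(orfs) >= pos)
        if (!length(hits)) return("intergenic")
        effs <- vapply(hits, function(h) {
            o <- orfs[h]
            if (as.character(strand(o)) == "+") {
                off <- pos - start(o)
                c0 <- start(o) + 3L * (off %/% 3L)
                codon <- chars[[chrom]][c0:(c0 + 2L)]
                mut <- codon; mut[pos - c0 + 1L] <- alt
                refC <- paste(codon, collapse = "")
                altC <- paste(mut, collapse = "")
            } else {
                off <- end(o) - pos
                cEnd <- end(o) - 3L * (off %/% 3L)
                codon <- chars[[chrom]][(cEnd - 2L):cEnd]
                mut <- codon; mut[3L - (cEnd - pos)] <- alt
                refC <- .revcompChar(paste(codon, collapse = ""))
                altC <- .revcompChar(paste(mut, collapse = ""))
            }
            refAA <- gc[[refC]]; altAA <- gc[[altC]]
            if (refAA == altAA) "synonymous"
            else if (altAA == "*") "stop_gain"
            else if (refAA == "*") "stop_loss"
            else "nonsynonymous"
        }, "")
        effs[which.max(severity[effs])]
    }, "")
}

#' Equivalent indel region
#'
#' The interval of all alternative placements of an indel that yield an
#' identical edited sequence (the ambiguity arising in homopolymer and
#' microsatellite context). The indel is anchored VCF-style: \code{pos} is
#' the base after which the insertion is placed, or after which the
#' deleted bases start; a shared leading base between \code{ref} and
#' \code{alt} is stripped automatically. For a deletion the region covers
#' every base deletable under some equivalent placement; for an insertion
#' it covers every anchor position.
#'
#' @param sequence Character scalar, the (local) sequence context.
#' @param pos Anchor position, 1-based within \code{sequence}.
#' @param ref Deleted bases ("" for a pure insertion).
#' @param alt Inserted bases ("" for a pure deletion).
#' @return Integer vector \code{c(start, end)} within \code{sequence}.
#' @export
equivalentIndelRegion <- function(sequence, pos, ref, alt) {
    norm <- .stripIndel(pos, ref, alt)
    pos <- norm$pos; ref <- norm$ref; alt <- norm$alt
    if (nchar(ref) > 0L && nchar(alt) > 0L)
        .stopf("complex substitutions have no equivalent region; normalize first")
    if (nchar(ref) == 0L && nchar(alt) == 0L)
        .stopf("not an indel")
    s <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    L <- length(s)
    edited <- function(anchor) {
        if (nchar(alt)) paste(c(s[seq_len(anchor)], alt,
                                if (anchor < L) s[(anchor + 1L):L]),
                              collapse = "")
        else {
            k <- nchar(ref)
            if (anchor + k > L) return(NA_character_)
            paste(s[-((anchor + 1L):(anchor + k))], collapse = "")
        }
    }
    target <- edited(pos)
    ## Equivalent anchors are spaced by the repeat period of the edited
    ## context, which never exceeds the indel length, so the scan may
    ## stop after `len` consecutive non-equivalent anchors.
    len <- max(nchar(ref), nchar(alt))
    lo <- pos
    a <- pos; miss <- 0L
    while (a > 0L && miss < len) {
        a <- a - 1L
        e <- edited(a)
        if (!is.na(e) && e == target) { lo <- a; miss <- 0L }
        else miss <- miss + 1L
    }
    hi <- pos
    maxAnchor <- if (nchar(alt)) L else L - nchar(ref)
    a <- pos; miss <- 0L
    while (a < maxAnchor && miss < len) {
        a <- a + 1L
        e <- edited(a)
        if (!is.na(e) && e == target) { hi <- a; miss <- 0L }
        else miss <- miss + 1L
    }
    if (nchar(ref)) c(lo + 1L, hi + nchar(ref))       # deleted-base span
    else c(max(1L, lo), hi)                            # anchor span
}

.stripIndel <- function(pos, ref, alt) {
    ## strip the common VCF anchor base / shared prefix
    while (nchar(ref) > 0L && nchar(alt) > 0L &&
           substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
        ref <- substr(ref, 2L, nchar(ref))
        alt <- substr(alt, 2L, nchar(alt))
        pos <- pos + 1L
    }
    list(pos = pos, ref = ref, alt = alt)
}

#' Classify an indel's effect on an ORF
#'
#' An indel affects an ORF only if its equivalent region is completely
#' contained within the ORF; a contained indel is a frameshift when its
#' length is not a multiple of 3, in-frame otherwise.
#'
#' @param genome An \linkS4class{AnnotatedGenome}.
#' @param chrom,pos,ref,alt Indel in anchored coordinates (see
#'   \code{\link{equivalentIndelRegion}}).
#' @param orf A single-range \code{GRanges} (the ORF).
#' @return One of \code{"frameshift"}, \code{"in_frame"},
#'   \code{"not_in_orf"}.
#' @export
classifyIndelOrfEffect <- function(genome, chrom, pos, ref, alt, orf) {
    eq <- .genomicEquivalentRegion(genome, chrom, pos, ref, alt)
    len <- abs(nchar(ref) - nchar(alt))
    if (as.character(seqnames(orf)) != chrom ||
        eq[1L] < start(orf) || eq[2L] > end(orf)) return("not_in_orf")
    if (len %% 3L == 0L) "in_frame" else "frameshift"
}

.genomicEquivalentRegion <- function(genome, chrom, pos, ref, alt,
                                     flank = 60L) {
    seqs <- genomeSequences(genome)
    L <- width(seqs)[match(chrom, names(seqs))]
    len <- max(nchar(ref), nchar(alt))
    a <- max(1L, pos - flank)
    b <- min(L, pos + len + flank)
    ctx <- as.character(Biostrings::subseq(seqs[[chrom]], a, b))
    eq <- equivalentIndelRegion(ctx, pos - a + 1L, ref, alt)
    c(a + eq[1L] - 1L, a + eq[2L] - 1L)
}

#' Call loss-of-function variants
#'
#' Loss-of-function variants are premature-stop SNPs and frameshifting
#' indels (equivalent region fully inside the ORF), excluding dubious
#' ORFs and variants in the very 3' end of the gene (relative position at
#' or beyond \code{1 - threePrimeCut}, default the last 2 percent of the
#' ORF), where truncation usually spares protein function.
#'
#' @param variants data.frame with \code{variant_id}, \code{type}
#'   (\code{"snp"}, \code{"ins"} or \code{"del"}), \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}.
#' @param carriers Logical matrix (variants x strains).
#' @param genome An \linkS4class{AnnotatedGenome}.
#' @param excludeDubious Drop calls in dubious ORFs (default TRUE).
#' @param threePrimeCut Excluded 3'-terminal fraction of the ORF.
#' @return List: \code{calls} (data.frame \code{orf_id}, \code{strain},
#'   \code{variant_id}, \code{kind}, \code{rel_pos}) and \code{perGene}
#'   (affected-strain counts per ORF).
#' @export
callLof <- function(variants, carriers, genome, excludeDubious = TRUE,
                    threePrimeCut = 0.02) {
    orfs <- orfAnnotation(genome)
    if (excludeDubious) orfs <- orfs[mcols(orfs)$class != "dubious"]
    calls <- list()
    for (i in seq_len(nrow(variants))) {
        v <- variants[i, ]
        hits <- which(as.character(seqnames(orfs)) == v$chrom &
                      start(orfs) <= v$pos & end(orfs) >= v$pos)
        for (h in hits) {
            o <- orfs[h]
            if (v$type == "snp") {
                eff <- classifySnpEffect(
                    data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref,
                               alt = v$alt), genome)
                if (eff != "stop_gain") next
                kind <- "premature_stop"
                rel <- .relPosInOrf(v$pos, v$pos, o)
            } else {
                effI <- classifyIndelOrfEffect(genome, v$chrom, v$pos,
                                               v$ref, v$alt, o)
                if (effI != "frameshift") next
                kind <- "frameshift"
                eq <- .genomicEquivalentRegion(genome, v$chrom, v$pos,
                                               v$ref, v$alt)
                rel <- .relPosInOrf(eq[1L], eq[2L], o)
            }
            if (rel >= 1 - threePrimeCut) next
            who <- colnames(carriers)[carriers[i, ]]
            for (s in who)
                calls[[length(calls) + 1L]] <- data.frame(
                    orf_id = mcols(o)$orf_id, strain = s,
                    variant_id = v$variant_id, kind = kind, rel_pos = rel)
        }
    }
    calls <- if (length(calls)) do.call(rbind, calls) else
        data.frame(orf_id = character(), strain = character(),
                   variant_id = character(), kind = character(),
                   rel_pos = numeric())
    perGene <- if (nrow(calls)) {
        agg <- stats::aggregate(strain ~ orf_id, calls,
                                function(x) length(unique(x)))
        names(agg)[2L] <- "n_strains"
        agg$n_variants <- stats::aggregate(variant_id ~ orf_id, calls,
            function(x) length(unique(x)))$variant_id
        agg
    } else data.frame(orf_id = character(), n_strains = integer(),
                      n_variants = integer())
    list(calls = calls, perGene = perGene)
}

## 5'-relative position of an interval within an ORF, in [0, 1).
.relPosInOrf <- function(s, e, orf) {
    if (as.character(strand(orf)) == "+")
        (s - start(orf)) / width(orf)
    else
        (end(orf) - e) / width(orf)
}

#' 3'-tail positional enrichment of loss-of-function variants
#'
#' Fold enrichment of calls falling in the terminal \code{tailFraction}
#' of the ORF relative to a uniform expectation, with an exact binomial
#' upper-tail p-value.
#'
#' @param relPositions Relative variant positions in [0, 1).
#' @param tailFraction Tail width (default 0.05, the last 5 percent).
#' @return List: \code{fold}, \code{p}, \code{nTail}, \code{n}.
#' @export
positionalEnrichment <- function(relPositions, tailFraction = 0.05) {
    n <- length(relPositions)
    k <- sum(relPositions >= 1 - tailFraction)
    fold <- (k / n) / tailFraction
    p <- stats::pbinom(k - 1L, n, tailFraction, lower.tail = FALSE)
    list(fold = fold, p = p, nTail = k, n = n)
}

#' Frame-preservation spectrum of indels
#'
#' Compares indel lengths inside ORFs with those in noncoding sequence:
#' under purifying selection against frameshifts, in-ORF indels are
#' enriched for lengths that are multiples of three. Reports per-length
#' counts, the 2x2 sample odds ratio (in-ORF x multiple-of-3) and a
#' two-sided Fisher exact p-value.
#'
#' @param lengths Integer indel lengths.
#' @param inOrf Logical, indel inside an ORF.
#' @return List: \code{table} (2x2), \code{oddsRatio}, \code{p},
#'   \code{perLength} (data.frame of counts by length and location).
#' @export
framePreservationSpectrum <- function(lengths, inOrf) {
    mod3 <- lengths %% 3L == 0L
    tab <- matrix(c(sum(inOrf & mod3), sum(inOrf & !mod3),
                    sum(!inOrf & mod3), sum(!inOrf & !mod3)),
                  nrow = 2L, byrow = TRUE,
                  dimnames = list(c("in_orf", "noncoding"),
                                  c("mod3", "not_mod3")))
    orr <- (tab[1L, 1L] * tab[2L, 2L]) / (tab[1L, 2L] * tab[2L, 1L])
    p <- stats::fisher.test(tab)$p.value
    perLength <- as.data.frame(table(length = lengths,
                                     location = ifelse(inOrf, "in_orf",
                                                       "noncoding")))
    list(table = tab, oddsRatio = orr, p = p, perLength = perLength)
}
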