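#' Candidate homolog alignments for reference ORFs in an assembly
#'
#' Aligns each reference ORF sequence against a strain assembly and
#' reports candidate placements: alignment blocks landing on one scaffold
#' are chained when closer than \code{chainGap}, and each chain becomes a
#' candidate with \code{score} (summed block length) and
#' \code{similarity} (fraction of the ORF covered by aligned blocks;
#' identity-weighted). Candidates below \code{minSimilarity} or with
#' score below \code{topFraction} of the per-query maximum are dropped,
#' and \code{is_top} marks candidates scoring within 10 percent of the
#' per-query maximum.
#'
#' @param ref An \linkS4class{AnnotatedGenome} (reference; dubious ORFs
#'   are skipped).
#' @param assembly \code{DNAStringSet} of assembly scaffolds.
#' @param aligner Alignment-block engine.
#' @param minSimilarity Similarity cutoff (default 0.9).
#' @param topFraction Score cutoff relative to the per-query top (0.9).
#' @param chainGap Maximum gap when chaining blocks (bp).
#' @return data.frame \code{query}, \code{scaffold}, \code{start},
#'   \code{end}, \code{strand}, \code{similarity}, \code{score},
#'   \code{is_top}.
#' @export
homologCandidates <- function(ref, assembly,
                              aligner = exactSeedAligner(),
                              minSimilarity = 0.9, topFraction = 0.9,
                              chainGap = 2000L) {
    orfs <- orfAnnotation(ref)
    orfs <- orfs[mcols(orfs)$class != "dubious"]
    seqs <- genomeSequences(ref)
    out <- list()
    for (i in seq_along(orfs)) {
        o <- orfs[i]
        oseq <- Biostrings::subseq(seqs[[as.character(seqnames(o))]],
                                   start(o), end(o))
        if (as.character(strand(o)) == "-")
            oseq <- Biostrings::reverseComplement(oseq)
        q <- DNAStringSet(oseq)
        names(q) <- mcols(o)$orf_id
        bl <- aligner(q, assembly)
        if (!nrow(bl)) next
        for (tn in unique(bl$tname)) {
            b <- bl[bl$tname == tn, , drop = FALSE]
            b <- b[order(b$tstart), , drop = FALSE]
            cl <- cumsum(c(1L, diff(b$tstart) > chainGap))
            for (g in unique(cl)) {
                bg <- b[cl == g, , drop = FALSE]
                ## identity over the aligned span: matched bases over
                ## matched plus the (mismatch) gaps between chained blocks
                qint <- IRanges::reduce(IRanges(bg$qstart, bg$qend))
                covered <- sum(width(qint))
                gaps <- if (length(qint) > 1L)
                    sum(start(qint)[-1L] -
                        end(qint)[-length(qint)] - 1L) else 0L
                matched <- sum(bg$length * bg$identity)
                out[[length(out) + 1L]] <- data.frame(
                    query = mcols(o)$orf_id, scaffold = tn,
                    start = min(bg$tstart), end = max(bg$tend),
                    strand = names(which.max(table(bg$strand))),
                    similarity = matched / (covered + gaps),
                    score = matched)
            }
        }
    }
    if (!length(out))
        return(data.frame(query = character(), scaffold = character(),
                          start = integer(), end = integer(),
                          strand = character(), similarity = numeric(),
                          score = numeric(), is_top = logical()))
    cand <- do.call(rbind, out)
    cand <- cand[cand$similarity > minSimilarity, , drop = FALSE]
    if (nrow(cand)) {
        top <- tapply(cand$score, cand$query, max)
        cand <- cand[cand$score >= topFraction * top[cand$query], ,
                     drop = FALSE]
        cand$is_top <- cand$score >= 0.9 * top[cand$query]
    }
    rownames(cand) <- NULL
    cand
}

#' Synteny and scaffold-edge support flags for candidates
#'
#' A candidate has synteny support on a side when the nearest
#' provisionally placed gene on that side of the scaffold is a reference
#' neighbor of the query (same reference chromosome, at most
#' \code{syntenyWindow} intervening genes). Provisional placements are
#' each query's top-scoring candidate. A side counts as at the scaffold
#' edge when the candidate lies within \code{edgeDistance} of the
#' scaffold end.
#'
#' @param candidates Candidate table (see
#'   \code{\link{homologCandidates}}).
#' @param ref An \linkS4class{AnnotatedGenome} (reference gene order).
#' @param scaffoldLengths Named scaffold lengths in bp (for edge flags).
#' @param syntenyWindow Maximum intervening genes (default 2).
#' @param edgeDistance Edge proximity in bp (default 2000).
#' @return The candidate table with \code{synteny_left},
#'   \code{synteny_right}, \code{at_edge} columns added.
#' @export
syntenyFlags <- function(candidates, ref, scaffoldLengths = NULL,
                         syntenyWindow = 2L, edgeDistance = 2000L) {
    orfs <- orfAnnotation(ref)
    ord <- order(as.character(seqnames(orfs)), start(orfs))
    refRank <- stats::setNames(seq_along(ord), mcols(orfs)$orf_id[ord])
    refChrom <- stats::setNames(as.character(seqnames(orfs)),
                                mcols(orfs)$orf_id)
    ## provisional placement: top-scoring candidate per query
    prov <- candidates[order(candidates$query, -candidates$score), ,
                       drop = FALSE]
    prov <- prov[!duplicated(prov$query), , drop = FALSE]
    candidates$synteny_left <- FALSE
    candidates$synteny_right <- FALSE
    candidates$at_edge <- FALSE
    isNeighbor <- function(q1, q2) {
        !is.na(refRank[q1]) && !is.na(refRank[q2]) &&
            refChrom[q1] == refChrom[q2] &&
            abs(refRank[q1] - refRank[q2]) <= syntenyWindow + 1L
    }
    for (i in seq_len(nrow(candidates))) {
        c1 <- candidates[i, ]
        others <- prov[prov$scaffold == c1$scaffold &
                       prov$query != c1$query, , drop = FALSE]
        left <- others[others$end < c1$start, , drop = FALSE]
        right <- others[others$start > c1$end, , drop = FALSE]
        if (nrow(left)) {
            nb <- left$query[which.max(left$end)]
            candidates$synteny_left[i] <- isNeighbor(c1$query, nb)
        }
        if (nrow(right)) {
            nb <- right$query[which.min(right$start)]
            candidates$synteny_right[i] <- isNeighbor(c1$query, nb)
        }
        ## a side with no placed gene between the candidate and the
        ## scaffold end counts as being at the edge, as does physical
        ## proximity to the end
        edgeLeft <- nrow(left) == 0L || c1$start <= edgeDistance
        edgeRight <- nrow(right) == 0L
        if (!is.null(scaffoldLengths)) {
            L <- scaffoldLengths[[c1$scaffold]]
            edgeRight <- edgeRight || c1$end >= L - edgeDistance
        }
        candidates$at_edge[i] <- edgeLeft || edgeRight
    }
    candidates
}

#' Assign one homolog placement per reference ORF
#'
#' Selects among pre-filtered candidates in priority order: (1)
#' top-scoring candidates with synteny support on both sides; (2)
#' top-scoring candidates with synteny on one side and the scaffold edge
#' on the other; (3) non-top candidates with synteny on both sides. The
#' first non-empty tier wins; ties are broken by higher score, longer
#' interval, then coordinates, so assignment is a pure function of the
#' candidate set. Queries with no qualifying candidate stay unassigned.
#'
#' @param candidates Candidate table with \code{is_top},
#'   \code{synteny_left}, \code{synteny_right}, \code{at_edge} columns
#'   (see \code{\link{syntenyFlags}}).
#' @return data.frame of assignments: \code{query}, \code{scaffold},
#'   \code{start}, \code{end}, \code{strand}, \code{score},
#'   \code{similarity}, \code{tier}.
#' @export
assignHomologs <- function(candidates) {
    out <- list()
    for (q in sort(unique(candidates$query))) {
        cc <- candidates[candidates$query == q, , drop = FALSE]
        tier1 <- cc$is_top & cc$synteny_left & cc$synteny_right
        tier2 <- cc$is_top & ((cc$synteny_left & !cc$synteny_right &
                               cc$at_edge) |
                              (!cc$synteny_left & cc$synteny_right &
                               cc$at_edge))
        tier3 <- !cc$is_top & cc$synteny_left & cc$synteny_right
        pick <- NULL
        for (t in 1:3) {
            sel <- switch(t, tier1, tier2, tier3)
            if (any(sel)) {
                cs <- cc[sel, , drop = FALSE]
                cs <- cs[order(-cs$score, -(cs$end - cs$start + 1L),
                               cs$scaffold, cs$start), , drop = FALSE]
                pick <- cbind(cs[1L, ], tier = t)
                break
            }
        }
        if (!is.null(pick)) out[[length(out) + 1L]] <- pick
    }
    if (!length(out))
        return(data.frame(query = character(), scaffold = character(),
                          start = integer(), end = integer(),
                          strand = character(), similarity = numeric(),
                          score = numeric(), is_top = logical(),
                          synteny_left = logical(),
                          synteny_right = logical(), at_edge = logical(),
                          tier = integer()))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Resolve assignments that map to the same assembly locus
#'
#' Assignments whose intervals coincide within \code{tolerance} bp at
#' both ends (same scaffold) compete for the locus; one survives,
#' preferred by tier (perfect synteny plus top score first), then higher
#' score, then longer gene. Dropped assignments are reported in the
#' \code{"dropped"} attribute with the rule that removed them.
#'
#' @param assignments Assignment table from \code{\link{assignHomologs}}.
#' @param tolerance Maximum start and end discrepancy in bp (default
#'   100).
#' @return Deduplicated assignment table, with dropped rows in
#'   \code{attr(, "dropped")}.
#' @export
deduplicateAssignments <- function(assignments, tolerance = 100L) {
    n <- nrow(assignments)
    if (n < 2L) {
        attr(assignments, "dropped") <- assignments[0, ]
        return(assignments)
    }
    ## single-linkage clusters of conflicting assignments
    cluster <- seq_len(n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        if (assignments$scaffold[i] == assignments$scaffold[j] &&
            abs(assignments$start[i] - assignments$start[j]) < tolerance &&
            abs(assignments$end[i] - assignments$end[j]) < tolerance) {
            cluster[cluster == cluster[j]] <- cluster[i]
        }
    }
    keep <- logical(n)
    rule <- character(n)
    for (cl in unique(cluster)) {
        ix <- which(cluster == cl)
        if (length(ix) == 1L) { keep[ix] <- TRUE; next }
        a <- assignments[ix, , drop = FALSE]
        o <- order(a$tier, -a$score, -(a$end - a$start + 1L), a$query)
        keep[ix[o[1L]]] <- TRUE
        losers <- ix[o[-1L]]
        best <- a[o[1L], ]
        rule[losers] <- vapply(losers, function(l) {
            x <- assignments[l, ]
            if (x$tier > best$tier) "lower_priority_tier"
            else if (x$score < best$score) "lower_score"
            else "shorter_gene"
        }, "")
    }
    dropped <- assignments[!keep, , drop = FALSE]
    if (nrow(dropped)) dropped$rule <- rule[!keep]
    out <- assignments[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "dropped") <- dropped
    out
}

#' Classify ab initio predictions as nonreference genes
#'
#' A predicted gene is a nonreference gene when it (a) does not overlap
#' any assigned homolog interval, (b) has no similarity hit to any
#' reference gene covering at least 80 percent of its length, or at
#' least 200 bp, at identity of at least 0.90, and (c) is at least
#' \code{minLength} bp long.
#'
#' @param predicted \code{GRanges} of predicted gene intervals on the
#'   assembly (names used as ids).
#' @param predictedSeqs \code{DNAStringSet} of the predicted gene
#'   sequences (same names).
#' @param refGeneSeqs \code{DNAStringSet} of reference gene sequences.
#' @param assigned \code{GRanges} of assigned homolog intervals.
#' @param aligner Alignment-block engine.
#' @param minLength Minimum gene length (default 300 bp).
#' @return Character vector of nonreference gene ids.
#' @export
classifyNonreferenceGenes <- function(predicted, predictedSeqs,
                                      refGeneSeqs, assigned,
                                      aligner = exactSeedAligner(),
                                      minLength = 300L) {
    ids <- names(predicted)
    keep <- width(predicted) >= minLength
    if (length(assigned))
        keep <- keep & !IRanges::overlapsAny(predicted, assigned)
    novel <- character()
    for (id in ids[keep]) {
        qseq <- predictedSeqs[id]
        qlen <- width(qseq)
        bl <- aligner(qseq, refGeneSeqs)
        hit <- nrow(bl) && any(bl$identity >= 0.90 &
                               (bl$length >= 0.8 * qlen |
                                bl$length >= 200L))
        if (!hit) novel <- c(novel, id)
    }
    novel
}

#' Naive single-exon ORF finder
#'
#' Longest open reading frames (ATG to stop, both strands) of at least
#' \code{minLength} bp. A deliberately simple stand-in for an ab initio
#' gene predictor, sufficient for synthetic assemblies whose genes are
#' intronless.
#'
#' @param seqs \code{DNAStringSet}.
#' @param minLength Minimum ORF length in bp (default 300).
#' @return \code{GRanges} of predicted ORFs (names \code{pred1...}).
#' @export
findOrfsNaive <- function(seqs, minLength = 300L) {
    out <- list()
    for (si in seq_along(seqs)) {
        L <- width(seqs)[si]
        nm <- names(seqs)[si]
        for (str in c("+", "-")) {
            s <- if (str == "+") seqs[[si]] else
                Biostrings::reverseComplement(seqs[[si]])
            chars <- strsplit(as.character(s), "", fixed = TRUE)[[1L]]
            for (frame in 0:2) {
                idx <- seq.int(1L + frame, length(chars) - 2L, by = 3L)
                codons <- paste0(chars[idx], chars[idx + 1L],
                                 chars[idx + 2L])
                stops <- c(0L, which(codons %in% .STOP_CODONS),
                           length(codons) + 1L)
                for (k in seq_len(length(stops) - 1L)) {
                    lo <- stops[k] + 1L; hi <- stops[k + 1L]
                    if (hi > length(codons)) next  # no terminal stop
                    starts <- which(codons[lo:hi] == "ATG")
                    if (!length(starts)) next
                    a <- lo + starts[1L] - 1L
                    w <- (hi - a + 1L) * 3L
                    if (w < minLength) next
                    sPos <- idx[a]
                    ePos <- idx[hi] + 2L
                    if (str == "-") {
                        tmp <- L - ePos + 1L
                        ePos <- L - sPos + 1L
                        sPos <- tmp
                    }
                    out[[length(out) + 1L]] <- data.frame(
                        chrom = nm, start = sPos, end = ePos,
                        strand = str)
                }
            }
        }
    }
    if (!length(out)) return(GRanges())
    df <- do.call(rbind, out)
    gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
    names(gr) <- sprintf("pred%03d", seq_along(gr))
    gr
}
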