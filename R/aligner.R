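#' Built-in exact seed-and-extend block aligner
#'
#' Returns an aligner function satisfying the alignment-block contract
#' used by the genome-content module: given a query and a target
#' \code{DNAStringSet} it returns a data.frame of local alignment blocks
#' with \code{qname}, \code{qstart}, \code{qend}, \code{tname},
#' \code{tstart}, \code{tend}, \code{strand}, \code{length},
#' \code{identity}. This engine reports maximal exact matches seeded on
#' shared k-mers (identity 1), on both target strands. Any other engine
#' producing blocks with lengths and identities (e.g. an external
#' nucleotide search tool) can be dropped in instead.
#'
#' Maximal exact matches on the same alignment diagonal separated by no
#' more than \code{maxGap} bp (isolated substitutions between two exact
#' runs) are chained into a single block whose identity is the matched
#' fraction of its span, so blocks tolerate point mismatches the way the
#' coverage rules assume.
#'
#' @param k Seed k-mer length (4-32, default 20).
#' @param minLen Minimum reported block span (default 50, the shortest
#'   block any coverage rule can use).
#' @param maxGap Maximum same-diagonal gap chained into one block.
#' @param bothStrands Also match against the reverse complement of the
#'   target.
#' @return A function \code{(query, target) -> data.frame}.
#' @export
exactSeedAligner <- function(k = 20L, minLen = 50L, maxGap = 200L,
                             bothStrands = TRUE) {
    force(k); force(minLen); force(maxGap); force(bothStrands)
    function(query, target) {
        if (is(query, "DNAString")) query <- DNAStringSet(query)
        if (is(target, "DNAString")) target <- DNAStringSet(target)
        if (!length(query) || !length(target) ||
            sum(width(query)) == 0L || sum(width(target)) == 0L)
            .stopf("empty query or target")
        out <- list()
        for (qi in seq_along(query)) {
            qseq <- as.character(query[[qi]])
            for (ti in seq_along(target)) {
                tseq <- as.character(target[[ti]])
                fwd <- .chainDiagonal(.exactMatchBlocks(qseq, tseq, k, k),
                                      maxGap, minLen)
                if (nrow(fwd)) {
                    fwd$strand <- "+"
                    fwd$qname <- names(query)[qi]
                    fwd$tname <- names(target)[ti]
                    out[[length(out) + 1L]] <- fwd
                }
                if (bothStrands) {
                    rc <- as.character(
                        Biostrings::reverseComplement(target[[ti]]))
                    rev <- .chainDiagonal(
                        .exactMatchBlocks(qseq, rc, k, k), maxGap, minLen)
                    if (nrow(rev)) {
                        tn <- nchar(tseq)
                        ts <- tn - rev$tend + 1L
                        rev$tend <- tn - rev$tstart + 1L
                        rev$tstart <- ts
                        rev$strand <- "-"
                        rev$qname <- names(query)[qi]
                        rev$tname <- names(target)[ti]
                        out[[length(out) + 1L]] <- rev
                    }
                }
            }
        }
        if (!length(out))
            return(data.frame(qname = character(), qstart = integer(),
                              qend = integer(), tname = character(),
                              tstart = integer(), tend = integer(),
                              strand = character(), length = integer(),
                              identity = numeric()))
        out <- do.call(rbind, out)
        out[, c("qname", "qstart", "qend", "tname", "tstart", "tend",
                "strand", "length", "identity")]
    }
}

## Chain exact blocks sharing a diagonal (qstart - tstart) when the gap
## between them is at most maxGap; identity = matched bases over span.
.chainDiagonal <- function(blocks, maxGap, minLen) {
    if (!nrow(blocks)) {
        blocks$length <- integer(0)
        return(blocks)
    }
    d <- blocks$qstart - blocks$tstart
    out <- list()
    for (diag in unique(d)) {
        b <- blocks[d == diag, , drop = FALSE]
        b <- b[order(b$qstart), , drop = FALSE]
        grp <- if (nrow(b) > 1L)
            cumsum(c(1L, b$qstart[-1L] - b$qend[-nrow(b)] - 1L > maxGap))
        else 1L
        for (g in unique(grp)) {
            bg <- b[grp == g, , drop = FALSE]
            qs <- min(bg$qstart); qe <- max(bg$qend)
            span <- qe - qs + 1L
            matched <- sum(bg$length)
            out[[length(out) + 1L]] <- data.frame(
                qstart = qs, qend = qe,
                tstart = min(bg$tstart), tend = max(bg$tend),
                length = span, identity = matched / span)
        }
    }
    res <- do.call(rbind, out)
    res[res$length >= minLen & res$identity >= 0.5, , drop = FALSE]
}
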