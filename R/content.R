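#' Find regions of a query genome absent from a target genome
#'
#' A query position counts as covered when it lies inside any alignment
#' block that is either at least 100 bp long with identity of at least
#' 0.75, or at least 50 bp long with identity of at least 0.90. Maximal
#' runs of uncovered positions of at least \code{minLength} bp (default
#' 1 kb) are reported as absent regions: query material with no
#' counterpart in the target. Coverage marking is a union over blocks, so
#' the result does not depend on block order.
#'
#' @param query,target \code{DNAStringSet} genomes (or single
#'   \code{DNAString}s).
#' @param aligner Alignment-block engine; default
#'   \code{\link{exactSeedAligner}()}.
#' @param minLength Minimum reported region length in bp (default 1000).
#' @param blocks Optional precomputed block table (skips the aligner).
#' @return data.frame \code{scaffold}, \code{start}, \code{end},
#'   \code{length}.
#' @export
findAbsentRegions <- function(query, target, aligner = exactSeedAligner(),
                              minLength = 1000L, blocks = NULL) {
    if (is(query, "DNAString")) query <- DNAStringSet(query)
    if (is.null(names(query)))
        names(query) <- sprintf("q%02d", seq_along(query))
    if (is.null(blocks)) blocks <- aligner(query, target)
    qualifying <- (blocks$length >= 100L & blocks$identity >= 0.75) |
        (blocks$length >= 50L & blocks$identity >= 0.90)
    blocks <- blocks[qualifying, , drop = FALSE]
    out <- list()
    for (qi in seq_along(query)) {
        qn <- names(query)[qi]
        L <- width(query)[qi]
        covered <- logical(L)
        b <- blocks[blocks$qname == qn, , drop = FALSE]
        for (r in seq_len(nrow(b)))
            covered[b$qstart[r]:b$qend[r]] <- TRUE
        runs <- .trueRuns(!covered)
        if (!nrow(runs)) next
        w <- runs[, "end"] - runs[, "start"] + 1L
        keep <- w >= minLength
        if (!any(keep)) next
        out[[length(out) + 1L]] <- data.frame(
            scaffold = qn, start = runs[keep, "start"],
            end = runs[keep, "end"], length = w[keep])
    }
    if (!length(out))
        return(data.frame(scaffold = character(), start = integer(),
                          end = integer(), length = integer()))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Pairwise genome content variation matrix
#'
#' For every ordered strain pair, the summed length of regions (over
#' \code{minLength} bp) present in the query strain but absent from the
#' target strain. The symmetric matrix adds both directions; the
#' directional totals are also returned.
#'
#' @param strains Named list of \code{DNAStringSet} genomes.
#' @param aligner Alignment-block engine (see
#'   \code{\link{findAbsentRegions}}).
#' @param minLength Minimum region length in bp.
#' @return List: \code{symmetric} (strain x strain bp matrix, diagonal
#'   0), \code{directional} (entry [i, j] = bp present in i, absent in
#'   j), \code{regions} (all absent regions, with \code{query} and
#'   \code{target} strain columns).
#' @export
contentVariationMatrix <- function(strains,
                                   aligner = exactSeedAligner(),
                                   minLength = 1000L) {
    n <- length(strains)
    nm <- names(strains)
    d <- matrix(0, n, n, dimnames = list(nm, nm))
    regions <- list()
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        reg <- findAbsentRegions(strains[[i]], strains[[j]],
                                 aligner = aligner, minLength = minLength)
        d[i, j] <- sum(reg$length)
        if (nrow(reg)) {
            reg$query <- nm[i]; reg$target <- nm[j]
            regions[[length(regions) + 1L]] <- reg
        }
    }
    regions <- if (length(regions)) do.call(rbind, regions) else
        data.frame(scaffold = character(), start = integer(),
                   end = integer(), length = integer(),
                   query = character(), target = character())
    list(symmetric = d + t(d), directional = d, regions = regions)
}

#' Correlate genome-content distance with SNP distance
#'
#' Pearson correlation over the upper-triangle strain pairs of the two
#' matrices (strains matched by name).
#'
#' @param contentMatrix,snpMatrix Symmetric matrices with shared strain
#'   labels.
#' @return List: \code{r}, \code{n} (number of pairs).
#' @export
correlateDistances <- function(contentMatrix, snpMatrix) {
    nm <- intersect(rownames(contentMatrix), rownames(snpMatrix))
    cm <- contentMatrix[nm, nm]
    sm <- snpMatrix[nm, nm]
    ut <- upper.tri(cm)
    r <- stats::cor(cm[ut], sm[ut])
    list(r = r, n = sum(ut))
}
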