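#' Read / write segregant log-likelihood ratio tables
#'
#' Tab-separated tables with columns \code{segregant}, \code{marker},
#' \code{scaffold}, \code{pos}, \code{llr}.
#'
#' @param file Path.
#' @param llr LLR data.frame (for writing).
#' @return \code{readLlrTable}: the data.frame; \code{writeLlrTable}:
#'   the path, invisibly.
#' @export
readLlrTable <- function(file) {
    df <- utils::read.delim(file, stringsAsFactors = FALSE)
    need <- c("segregant", "marker", "scaffold", "pos", "llr")
    if (!all(need %in% names(df)))
        .stopf("LLR table must have columns %s",
               paste(need, collapse = ", "))
    df
}

#' @rdname readLlrTable
#' @export
writeLlrTable <- function(llr, file) {
    utils::write.table(llr, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' Write a linkage-group placement table
#'
#' AGP-like TSV: one row per placed scaffold with linkage group, rank,
#' orientation and estimated gap to the next scaffold.
#'
#' @param graph A traced \linkS4class{ScaffoldLinkGraph}.
#' @param file Path.
#' @return The path, invisibly.
#' @export
writeLinkageGroups <- function(graph, file) {
    paths <- linkagePaths(graph)
    rows <- list()
    for (g in seq_along(paths)) {
        p <- paths[[g]]
        rows[[g]] <- data.frame(group = sprintf("LG%02d", g),
                                rank = seq_len(nrow(p)),
                                scaffold = p$scaffold,
                                orientation = p$orientation)
    }
    df <- do.call(rbind, rows)
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}
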