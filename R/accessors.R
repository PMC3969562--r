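#' @include AllClasses.R
NULL

#' Accessors for the central classes
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param x An object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeSequences", function(x) standardGeneric("genomeSequences"))

#' @rdname accessors
#' @export
setMethod("genomeSequences", "AnnotatedGenome", function(x) x@sequences)

#' @rdname accessors
#' @export
setGeneric("orfAnnotation", function(x) standardGeneric("orfAnnotation"))

#' @rdname accessors
#' @export
setMethod("orfAnnotation", "AnnotatedGenome", function(x) x@orfs)

#' @rdname accessors
#' @export
setGeneric("repeatAnnotation", function(x) standardGeneric("repeatAnnotation"))

#' @rdname accessors
#' @export
setMethod("repeatAnnotation", "AnnotatedGenome", function(x) x@repeats)

#' @rdname accessors
#' @export
setGeneric("subtelomereSpan", function(x) standardGeneric("subtelomereSpan"))

#' @rdname accessors
#' @export
setMethod("subtelomereSpan", "AnnotatedGenome", function(x) x@subtelomereSpan)

#' Subtelomeric intervals of a genome
#'
#' Returns the outermost \code{span} bp of each chromosome end as a
#' \code{GRanges} (clipped for chromosomes shorter than twice the span, in
#' which case the whole chromosome is subtelomeric).
#'
#' @param x An \code{AnnotatedGenome}.
#' @param span Override of the genome's subtelomere span in bp.
#' @return GRanges of subtelomeric regions.
#' @export
subtelomeres <- function(x, span = subtelomereSpan(x)) {
    seqs <- genomeSequences(x)
    lens <- width(seqs)
    nm <- names(seqs)
    chr <- character(); s <- integer(); e <- integer()
    for (i in seq_along(seqs)) {
        L <- lens[i]
        if (L <= 2L * span) {
            chr <- c(chr, nm[i]); s <- c(s, 1L); e <- c(e, L)
        } else {
            chr <- c(chr, nm[i], nm[i])
            s <- c(s, 1L, L - span + 1L)
            e <- c(e, span, L)
        }
    }
    GenomicRanges::reduce(GRanges(chr, IRanges(s, e)))
}

#' @rdname accessors
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname accessors
#' @export
setMethod("genotypeCalls", "GenotypeMatrix", function(x) x@calls)

#' @rdname accessors
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname accessors
#' @export
setMethod("markerInfo", "GenotypeMatrix", function(x) x@markers)

#' @rdname accessors
#' @export
setGeneric("segregantIds", function(x) standardGeneric("segregantIds"))

#' @rdname accessors
#' @export
setMethod("segregantIds", "GenotypeMatrix", function(x) rownames(x@calls))

#' @rdname accessors
#' @export
setGeneric("ldLambda", function(x) standardGeneric("ldLambda"))

#' @rdname accessors
#' @export
setMethod("ldLambda", "LdDecayModel", function(x) x@lambda)

#' @rdname accessors
#' @export
setGeneric("linkEdges", function(x) standardGeneric("linkEdges"))

#' @rdname accessors
#' @export
setMethod("linkEdges", "ScaffoldLinkGraph", function(x) x@edges)

#' @rdname accessors
#' @export
setGeneric("linkagePaths", function(x) standardGeneric("linkagePaths"))

#' @rdname accessors
#' @export
setMethod("linkagePaths", "ScaffoldLinkGraph", function(x) x@paths)

#' @rdname accessors
#' @export
setGeneric("unplacedScaffolds", function(x) standardGeneric("unplacedScaffolds"))

#' @rdname accessors
#' @export
setMethod("unplacedScaffolds", "ScaffoldLinkGraph", function(x) x@unplaced)

#' @rdname accessors
#' @export
setGeneric("depthWindows", function(x) standardGeneric("depthWindows"))

#' @rdname accessors
#' @export
setMethod("depthWindows", "DepthWindowTrack", function(x) x@windows)

#' @rdname accessors
#' @export
setGeneric("medianDepth", function(x) standardGeneric("medianDepth"))

#' @rdname accessors
#' @export
setMethod("medianDepth", "DepthWindowTrack", function(x) x@medianDepth)

setMethod("show", "AnnotatedGenome", function(object) {
    seqs <- genomeSequences(object)
    cat("AnnotatedGenome with", length(seqs), "sequence(s),",
        sum(width(seqs)), "bp total\n")
    cat("  ORFs:", length(object@orfs),
        "| repeats:", length(object@repeats),
        "| subtelomere span:", object@subtelomereSpan, "bp\n")
})

setMethod("show", "GenotypeMatrix", function(object) {
    cat("GenotypeMatrix:", nrow(object@calls), "segregants x",
        ncol(object@calls), "markers\n")
    cat(sprintf("  missing calls: %.1f%%\n",
                100 * mean(is.na(object@calls))))
})

setMethod("show", "LdDecayModel", function(object) {
    cat(sprintf(
        "LdDecayModel: r2 = exp(-lambda d), lambda = %.3e /bp (%d pairs, RSS %.3g)\n",
        object@lambda, object@nPairsUsed, object@fitResidual))
})

setMethod("show", "ScaffoldLinkGraph", function(object) {
    cat("ScaffoldLinkGraph:", nrow(object@nodes), "scaffolds,",
        nrow(object@edges), "edges,", length(object@paths),
        "linkage-group path(s),", nrow(object@unplaced), "unplaced\n")
})

setMethod("show", "DepthWindowTrack", function(object) {
    w <- object@windows
    cat("DepthWindowTrack:", length(w), "windows",
        if (length(w)) paste0("(", width(w)[1L], " bp)") else "",
        "| masked:", sum(mcols(w)$masked),
        "| median depth:", signif(object@medianDepth, 4), "\n")
})
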