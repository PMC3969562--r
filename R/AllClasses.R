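#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAStringSet
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' AnnotatedGenome: a genome with ORF, repeat and subtelomere annotation
#'
#' Container for a (simulated or real) genome: chromosome sequences, an ORF
#' table, repeat intervals and the span of the subtelomeric region at each
#' chromosome end. Subtelomeres default to the outermost 33 kb of each
#' chromosome, the convention used throughout yeast comparative genomics.
#'
#' @slot sequences A \link[Biostrings]{DNAStringSet}, one entry per
#'   chromosome or scaffold.
#' @slot orfs A \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{orf_id}, \code{class} (one of \code{"verified"},
#'   \code{"uncharacterized"}, \code{"dubious"}) and \code{essential}
#'   (logical).
#' @slot repeats A \code{GRanges} of repeat-associated intervals (masked in
#'   depth analyses).
#' @slot subtelomereSpan Integer scalar, bp taken as subtelomeric at each
#'   chromosome end (default 33000).
#'
#' @export
setClass("AnnotatedGenome",
    representation(
        sequences = "DNAStringSet",
        orfs = "GRanges",
        repeats = "GRanges",
        subtelomereSpan = "integer"
    ),
    prototype(subtelomereSpan = 33000L)
)

setValidity("AnnotatedGenome", function(object) {
    msg <- character()
    seqs <- object@sequences
    lens <- setNames(width(seqs), names(seqs))
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
        msg <- c(msg, "chromosome sequences must have unique names")
    if (length(object@subtelomereSpan) != 1L || object@subtelomereSpan < 0L)
        msg <- c(msg, "subtelomereSpan must be a single non-negative integer")
    if (length(object@orfs)) {
        need <- c("orf_id", "class", "essential")
        if (!all(need %in% colnames(mcols(object@orfs))))
            msg <- c(msg, "orfs must carry orf_id, class and essential columns")
        else {
            if (!all(mcols(object@orfs)$class %in%
                     c("verified", "uncharacterized", "dubious")))
                msg <- c(msg, "unknown ORF class label")
            if (any(width(object@orfs) %% 3L != 0L))
                msg <- c(msg, "ORF lengths must be multiples of 3")
        }
        bad <- .outOfBounds(object@orfs, lens)
        if (any(bad)) msg <- c(msg, "ORF intervals outside chromosome bounds")
    }
    if (length(object@repeats)) {
        bad <- .outOfBounds(object@repeats, lens)
        if (any(bad)) msg <- c(msg, "repeat intervals outside chromosome bounds")
    }
    if (length(msg)) msg else TRUE
})

.outOfBounds <- function(gr, lens) {
    chr <- as.character(seqnames(gr))
    unknown <- !(chr %in% names(lens))
    oob <- rep(TRUE, length(gr))
    ok <- !unknown
    oob[ok] <- start(gr)[ok] < 1L | end(gr)[ok] > lens[chr[ok]]
    oob | unknown
}

#' GenotypeMatrix: haploid segregant calls at mapped markers
#'
#' Segregants-by-markers matrix of haploid genotype calls in \{A, B,
#' missing\}, coded internally as integer 1 (parent A), 0 (parent B) and
#' \code{NA} (missing / intermediate likelihood). Markers carry their
#' scaffold and position so linkage disequilibrium can be related to
#' physical distance.
#'
#' @slot calls Integer matrix (segregants x markers) in \{1, 0, NA\}.
#' @slot markers A \link[S4Vectors]{DataFrame} with columns \code{marker},
#'   \code{scaffold}, \code{pos}, sorted by (scaffold, pos).
#' @export
setClass("GenotypeMatrix",
    representation(calls = "matrix", markers = "DFrame")
)

setValidity("GenotypeMatrix", function(object) {
    msg <- character()
    if (!is.integer(object@calls))
        msg <- c(msg, "calls must be an integer matrix")
    v <- object@calls[!is.na(object@calls)]
    if (length(v) && !all(v %in% c(0L, 1L)))
        msg <- c(msg, "calls must be 0, 1 or NA")
    if (!all(c("marker", "scaffold", "pos") %in% colnames(object@markers)))
        msg <- c(msg, "markers must have marker, scaffold, pos columns")
    else {
        if (nrow(object@markers) != ncol(object@calls))
            msg <- c(msg, "marker table and call matrix disagree in size")
        o <- order(object@markers$scaffold, object@markers$pos)
        if (!identical(o, seq_len(nrow(object@markers))))
            msg <- c(msg, "markers must be sorted by (scaffold, pos)")
    }
    if (length(msg)) msg else TRUE
})

#' LdDecayModel: exponential decay of linkage disequilibrium with distance
#'
#' Fit of the model r^2 = exp(-lambda * d), where d is physical distance in
#' bp, to within-scaffold marker pairs. The decay constant lambda converts
#' observed between-scaffold LD into estimated physical gaps.
#'
#' @slot lambda Decay rate per bp (> 0).
#' @slot fitResidual Residual sum of squares of the fit.
#' @slot nPairsUsed Number of marker pairs used.
#' @export
setClass("LdDecayModel",
    representation(lambda = "numeric", fitResidual = "numeric",
                   nPairsUsed = "integer")
)

setValidity("LdDecayModel", function(object) {
    if (length(object@lambda) != 1L || !is.finite(object@lambda) ||
        object@lambda <= 0) "lambda must be a single positive number" else TRUE
})

#' ScaffoldLinkGraph: LD-derived scaffold adjacency and linkage-group paths
#'
#' Nodes are assembly scaffolds; edges connect scaffold pairs whose corner
#' LD supports physical adjacency, carrying the inferred relative
#' orientation (FF, FR, RF, RR), the corner strength (mean corner r^2) and
#' an estimated gap. Paths are the traced linkage groups (ordered, oriented
#' scaffold lists); unplaced scaffolds are listed with a reason.
#'
#' @slot nodes DataFrame: \code{scaffold}, \code{length}, \code{n_markers}.
#' @slot edges DataFrame: \code{scaffold_i}, \code{scaffold_j},
#'   \code{orientation}, \code{strength}, \code{contrast}, \code{est_gap}.
#' @slot paths List of DataFrames (\code{scaffold}, \code{orientation}
#'   in \{"+","-"\}), one per linkage group.
#' @slot unplaced DataFrame: \code{scaffold}, \code{reason} in
#'   \{"no_orientation", "too_few_snps"\}.
#' @export
setClass("ScaffoldLinkGraph",
    representation(nodes = "DFrame", edges = "DFrame", paths = "list",
                   unplaced = "DFrame")
)

setValidity("ScaffoldLinkGraph", function(object) {
    msg <- character()
    placed <- unlist(lapply(object@paths, function(p) p$scaffold))
    if (anyDuplicated(placed))
        msg <- c(msg, "a scaffold appears in more than one path position")
    if (nrow(object@edges) &&
        !all(object@edges$orientation %in% c("FF", "FR", "RF", "RR")))
        msg <- c(msg, "edge orientation must be FF/FR/RF/RR")
    if (nrow(object@unplaced) &&
        !all(object@unplaced$reason %in% c("no_orientation", "too_few_snps")))
        msg <- c(msg, "unknown unplaced reason")
    if (length(msg)) msg else TRUE
})

#' DepthWindowTrack: windowed, median-normalized read depth
#'
#' Non-overlapping fixed-width windows tiling a genome, with raw mean
#' depth, depth normalized by the genome-wide median over unmasked windows,
#' the log2 of that ratio, and a mask flag (repeat / transposon-similar
#' windows are masked and excluded from normalization and calling).
#'
#' @slot windows GRanges with metadata columns \code{depth},
#'   \code{normalized}, \code{log2_ratio}, \code{masked}.
#' @slot medianDepth Genome-wide median raw depth over unmasked windows.
#' @slot strain Strain identifier (may be \code{NA}).
#' @export
setClass("DepthWindowTrack",
    representation(windows = "GRanges", medianDepth = "numeric",
                   strain = "character")
)

setValidity("DepthWindowTrack", function(object) {
    need <- c("depth", "normalized", "log2_ratio", "masked")
    if (!all(need %in% colnames(mcols(object@windows))))
        return("windows must carry depth, normalized, log2_ratio, masked")
    w <- object@windows
    bychr <- split(w, as.character(seqnames(w)))
    for (g in bychr) {
        s <- sort(g)
        if (length(s) > 1L && any(start(s)[-1L] <= end(s)[-length(s)]))
            return("windows overlap")
    }
    TRUE
})
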