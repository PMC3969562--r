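#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via \pkg{ape}), with taxa pre-sorted by
#' label so that tie-breaking is deterministic. Branch lengths may come
#' out negative; set \code{clampNegative} to truncate them at zero.
#'
#' @param dm Symmetric numeric matrix with zero diagonal and labelled
#'   rows/columns (at least 3 taxa).
#' @param clampNegative Truncate negative branch lengths at 0.
#' @return An unrooted \code{phylo} tree.
#' @export
neighborJoining <- function(dm, clampNegative = FALSE) {
    if (nrow(dm) < 3L) .stopf("neighbor joining needs at least 3 taxa")
    if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)))
        .stopf("distance matrix must be symmetric")
    o <- order(rownames(dm))
    tr <- ape::nj(dm[o, o])
    if (clampNegative) tr$edge.length <- pmax(tr$edge.length, 0)
    tr
}

#' Euclidean distance between CNV profiles
#'
#' Pairwise Euclidean distance between strains' per-window log2 depth
#' ratios over shared unmasked windows.
#'
#' @param tracks Named list of \linkS4class{DepthWindowTrack} over
#'   identical windows.
#' @return Symmetric distance matrix.
#' @export
cnvProfileDistance <- function(tracks) {
    l2 <- vapply(tracks, function(t) mcols(depthWindows(t))$log2_ratio,
                 numeric(length(depthWindows(tracks[[1L]]))))
    masked <- Reduce(`|`, lapply(tracks, function(t)
        mcols(depthWindows(t))$masked))
    as.matrix(stats::dist(t(l2[!masked, , drop = FALSE])))
}

#' Additive copy-number model for a phenotype
#'
#' Least-squares regression of phenotype on copy number. Reports the
#' slope, intercept, variance explained (R-squared, identical to the
#' squared Pearson correlation for a single predictor), the F-test
#' p-value, and per-copy group means for inspecting departures from
#' additivity.
#'
#' @param copies Numeric copy numbers per strain.
#' @param phenotype Numeric phenotype per strain.
#' @return List: \code{slope}, \code{intercept},
#'   \code{varianceExplained}, \code{p}, \code{groupMeans}, \code{n}.
#' @export
additiveCnModel <- function(copies, phenotype) {
    ok <- !is.na(copies) & !is.na(phenotype)
    copies <- copies[ok]; phenotype <- phenotype[ok]
    if (length(copies) < 3L) .stopf("need at least 3 strains")
    if (length(unique(copies)) < 2L)
        .stopf("copy number is constant; no association can be fit")
    fit <- stats::lm(phenotype ~ copies)
    ## a noiseless (perfect) fit triggers a harmless summary.lm warning
    sm <- suppressWarnings(summary(fit))
    p <- if (sm$sigma == 0) 0 else
        stats::pf(sm$fstatistic[1L], sm$fstatistic[2L], sm$fstatistic[3L],
                  lower.tail = FALSE)
    gm <- c(tapply(phenotype, copies, mean))
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         varianceExplained = sm$r.squared,
         p = unname(p),
         groupMeans = gm, n = length(copies))
}

#' Contrast phenotypes between two copy-number groups
#'
#' Welch two-sample comparison of the phenotype between strains with the
#' two named copy numbers (default 1 vs 2 copies, the contrast that
#' distinguishes additive from saturating copy-number effects).
#'
#' @param copies Numeric copy numbers per strain.
#' @param phenotype Numeric phenotype per strain.
#' @param groups Two copy-number values to contrast.
#' @return List: \code{difference} (mean of first group minus second),
#'   \code{p}, \code{n}.
#' @export
groupContrast <- function(copies, phenotype, groups = c(1, 2)) {
    x <- phenotype[copies == groups[1L]]
    y <- phenotype[copies == groups[2L]]
    if (length(x) < 2L || length(y) < 2L)
        .stopf("need at least 2 strains per group")
    diffMeans <- mean(x) - mean(y)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        p <- if (diffMeans == 0) 1 else 0
    } else {
        p <- stats::t.test(x, y)$p.value
    }
    list(difference = diffMeans, p = p, n = c(length(x), length(y)))
}
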