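## Corner-LD scaffold linking and linkage-group path tracing.

## Map an edge orientation to the two scaffold ends it joins.
## "S"/"E" are the low- and high-coordinate ends of the marker order.
.orientationEnds <- function(orientation) {
    switch(orientation,
           FF = c("E", "S"), FR = c("E", "E"),
           RF = c("S", "S"), RR = c("S", "E"))
}

#' Build LD-derived scaffold-scaffold links
#'
#' For each pair of scaffolds the matrix of between-scaffold r^2 values,
#' ordered by within-scaffold marker position, is summarized at its four
#' corners (mean r^2 over \code{cornerK} x \code{cornerK} corner blocks;
#' blocks shrink when a scaffold has fewer markers). The strongest corner
#' identifies which two scaffold ends are physically closest and hence
#' the relative orientation: FF = end of i adjacent to start of j,
#' FR = end-to-end, RF = start-to-start, RR = start of i to end of j.
#' An edge is emitted when the best corner strength reaches
#' \code{linkThreshold}; its orientation is considered reliable when the
#' best corner exceeds the second best by \code{orientationContrast}.
#' Scaffolds with fewer than two markers cannot be oriented and are
#' reported unplaced with reason \code{too_few_snps}.
#'
#' @param gm A \linkS4class{GenotypeMatrix}.
#' @param model Optional \linkS4class{LdDecayModel} used to convert corner
#'   strength into an estimated gap in bp.
#' @param cornerK Corner block size in markers (default 5; 1 reproduces a
#'   literal single-corner-element comparison).
#' @param linkThreshold Minimum best-corner mean r^2 for an edge.
#' @param orientationContrast Minimum margin of the best corner over the
#'   second best for the orientation to count as resolved.
#' @param scaffoldLengths Optional named lengths (bp) stored on the nodes.
#' @return A \linkS4class{ScaffoldLinkGraph} with nodes, edges and
#'   \code{too_few_snps} unplaced entries (paths still empty).
#' @export
buildScaffoldLinks <- function(gm, model = NULL, cornerK = 5L,
                               linkThreshold = 0.3,
                               orientationContrast = 0.05,
                               scaffoldLengths = NULL) {
    calls <- genotypeCalls(gm)
    info <- markerInfo(gm)
    scaffolds <- sort(unique(info$scaffold))
    byScf <- lapply(scaffolds, function(s) {
        ix <- which(info$scaffold == s)
        ix[order(info$pos[ix])]
    })
    names(byScf) <- scaffolds
    nMark <- lengths(byScf)
    lens <- if (!is.null(scaffoldLengths)) scaffoldLengths[scaffolds]
            else vapply(byScf, function(ix) max(info$pos[ix]), 0)
    nodes <- DataFrame(scaffold = scaffolds, length = as.numeric(lens),
                       n_markers = as.integer(nMark))
    tooFew <- scaffolds[nMark < 2L]
    eligible <- scaffolds[nMark >= 2L]

    r2 <- .ldMatrix(calls)
    edges <- list()
    if (length(eligible) >= 2L) {
        pairsIdx <- utils::combn(eligible, 2L)
        for (cc in seq_len(ncol(pairsIdx))) {
            a <- pairsIdx[1L, cc]; b <- pairsIdx[2L, cc]
            ia <- byScf[[a]]; ib <- byScf[[b]]
            M <- r2[ia, ib, drop = FALSE]
            mi <- nrow(M); mj <- ncol(M)
            ki <- min(cornerK, mi); kj <- min(cornerK, mj)
            corners <- c(
                RF = mean(M[1:ki, 1:kj], na.rm = TRUE),
                RR = mean(M[1:ki, (mj - kj + 1L):mj], na.rm = TRUE),
                FF = mean(M[(mi - ki + 1L):mi, 1:kj], na.rm = TRUE),
                FR = mean(M[(mi - ki + 1L):mi, (mj - kj + 1L):mj],
                          na.rm = TRUE))
            corners[is.nan(corners)] <- 0
            o <- order(corners, decreasing = TRUE)
            best <- corners[o[1L]]
            contrast <- best - corners[o[2L]]
            if (best >= linkThreshold) {
                edges[[length(edges) + 1L]] <- data.frame(
                    scaffold_i = a, scaffold_j = b,
                    orientation = names(corners)[o[1L]],
                    strength = unname(best), contrast = unname(contrast),
                    est_gap = if (!is.null(model))
                        estimateGap(min(unname(best), 1), model)
                    else NA_real_,
                    oriented = contrast >= orientationContrast)
            }
        }
    }
    edges <- if (length(edges)) do.call(rbind, edges) else
        data.frame(scaffold_i = character(), scaffold_j = character(),
                   orientation = character(), strength = numeric(),
                   contrast = numeric(), est_gap = numeric(),
                   oriented = logical())
    unpl <- DataFrame(scaffold = tooFew,
                      reason = rep("too_few_snps", length(tooFew)))
    new("ScaffoldLinkGraph", nodes = nodes, edges = DataFrame(edges),
        paths = list(), unplaced = unpl)
}

#' Trace linkage groups as simple paths through the scaffold link graph
#'
#' Greedy strongest-edge path extension: reliably oriented edges are
#' visited in decreasing corner strength and accepted when both scaffold
#' ends they join are still free and no cycle would form (a cycle-closing
#' edge, necessarily the weakest seen for that component, is dropped).
#' Accepted edges form simple paths, each reported as an ordered list of
#' oriented scaffolds, with the traversal direction fixed canonically so
#' the output is independent of input ordering. Scaffolds whose candidate
#' edges all have unresolved orientation (corner contrast below the
#' threshold used in \code{\link{buildScaffoldLinks}}) are listed as
#' unplaced with reason \code{no_orientation}; scaffolds with no edges at
#' all form singleton paths.
#'
#' @param graph A \linkS4class{ScaffoldLinkGraph} with edges.
#' @return The graph with \code{paths} and \code{unplaced} filled in.
#' @export
traceLinkageGroups <- function(graph) {
    nodes <- graph@nodes
    edges <- as.data.frame(graph@edges)
    tooFew <- as.character(graph@unplaced$scaffold)
    scf <- setdiff(as.character(nodes$scaffold), tooFew)

    usable <- edges[edges$oriented, , drop = FALSE]
    usable <- usable[order(-usable$strength, usable$scaffold_i,
                           usable$scaffold_j), , drop = FALSE]

    endUsed <- matrix(FALSE, length(scf), 2L,
                      dimnames = list(scf, c("S", "E")))
    parent <- seq_along(scf)
    findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    adj <- stats::setNames(vector("list", length(scf)), scf)
    accepted <- list()
    for (r in seq_len(nrow(usable))) {
        e <- usable[r, ]
        ends <- .orientationEnds(e$orientation)
        a <- e$scaffold_i; b <- e$scaffold_j
        if (!(a %in% scf) || !(b %in% scf)) next
        if (endUsed[a, ends[1L]] || endUsed[b, ends[2L]]) next
        ra <- findRoot(match(a, scf)); rb <- findRoot(match(b, scf))
        if (ra == rb) next  # would close a cycle; keep the path simple
        endUsed[a, ends[1L]] <- TRUE
        endUsed[b, ends[2L]] <- TRUE
        parent[ra] <- rb
        adj[[a]] <- c(adj[[a]], list(list(to = b, fromEnd = ends[1L],
                                          toEnd = ends[2L])))
        adj[[b]] <- c(adj[[b]], list(list(to = a, fromEnd = ends[2L],
                                          toEnd = ends[1L])))
        accepted[[length(accepted) + 1L]] <- e
    }

    degree <- lengths(adj)
    visited <- stats::setNames(rep(FALSE, length(scf)), scf)
    paths <- list()
    ## terminals first (degree <= 1), deterministic order by name
    for (s in scf[order(scf)]) {
        if (visited[s] || degree[s] != 1L) next
        path <- .walkPath(s, adj, visited)
        visited[path$visited] <- TRUE
        paths[[length(paths) + 1L]] <- path$df
    }
    ## canonical direction: first scaffold name <= last
    paths <- lapply(paths, function(p) {
        if (nrow(p) > 1L &&
            p$scaffold[nrow(p)] < p$scaffold[1L]) {
            p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
            p$orientation <- ifelse(p$orientation == "+", "-", "+")
            rownames(p) <- NULL
        }
        p
    })
    ## order paths by their first scaffold for determinism
    paths <- paths[order(vapply(paths, function(p) p$scaffold[1L], ""))]

    inPath <- unlist(lapply(paths, function(p) p$scaffold))
    leftover <- setdiff(scf, inPath)
    hadEdge <- unique(c(edges$scaffold_i, edges$scaffold_j))
    noOrient <- leftover[leftover %in% hadEdge]
    singletons <- setdiff(leftover, noOrient)
    for (s in sort(singletons))
        paths[[length(paths) + 1L]] <-
            data.frame(scaffold = s, orientation = "+")

    unpl <- DataFrame(
        scaffold = c(tooFew, sort(noOrient)),
        reason = c(rep("too_few_snps", length(tooFew)),
                   rep("no_orientation", length(noOrient))))
    new("ScaffoldLinkGraph", nodes = nodes, edges = graph@edges,
        paths = paths, unplaced = unpl)
}

## Walk a simple path starting from a terminal scaffold.
.walkPath <- function(startScf, adj, visited) {
    scaffolds <- character(); orient <- character()
    cur <- startScf
    enterEnd <- NA_character_
    prev <- NA_character_
    repeat {
        links <- adj[[cur]]
        nxt <- NULL
        for (l in links) if (is.na(prev) || l$to != prev) { nxt <- l; break }
        if (is.na(enterEnd)) {
            ## terminal: orientation follows the exit end (or "+" if alone)
            exitEnd <- if (!is.null(nxt)) nxt$fromEnd else "E"
            orient <- c(orient, if (exitEnd == "E") "+" else "-")
        } else {
            orient <- c(orient, if (enterEnd == "S") "+" else "-")
        }
        scaffolds <- c(scaffolds, cur)
        if (is.null(nxt)) break
        prev <- cur
        enterEnd <- nxt$toEnd
        cur <- nxt$to
        if (cur %in% scaffolds) break  # safety; cycles are prevented above
    }
    list(df = data.frame(scaffold = scaffolds, orientation = orient),
         visited = scaffolds)
}

#' Score scaffold recovery against a truth placement
#'
#' Compares traced linkage-group paths with the placement table emitted by
#' \code{\link{fragmentGenome}}. Each path is compared in both traversal
#' directions and the better one is scored (a linkage group has no
#' intrinsic left-right direction). Ordering concordance is the fraction
#' of within-path scaffold pairs whose order matches the truth ranks
#' (pairs mixing chromosomes count as discordant); orientation accuracy
#' is the fraction of scaffolds in multi-scaffold paths whose orientation
#' matches the truth strand under the chosen direction.
#'
#' @param graph A traced \linkS4class{ScaffoldLinkGraph}.
#' @param placement Truth placement from \code{\link{fragmentGenome}}.
#' @return List: \code{orderConcordance}, \code{orientationAccuracy},
#'   \code{nPlaced}, \code{nUnplaced}.
#' @export
scaffoldRecoveryStats <- function(graph, placement) {
    rownames(placement) <- placement$scaffold
    concordant <- 0L; totalPairs <- 0L
    orientOk <- 0L; orientTot <- 0L
    for (p in linkagePaths(graph)) {
        if (nrow(p) < 2L) next
        scoreDir <- function(df) {
            tr <- placement[df$scaffold, , drop = FALSE]
            conc <- 0L; tot <- 0L
            n <- nrow(df)
            for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
                tot <- tot + 1L
                if (tr$chrom[i] == tr$chrom[j] && tr$rank[i] < tr$rank[j])
                    conc <- conc + 1L
            }
            ok <- sum(df$orientation == tr$strand)
            list(conc = conc, tot = tot, ok = ok)
        }
        fwd <- scoreDir(p)
        rv <- p[rev(seq_len(nrow(p))), , drop = FALSE]
        rv$orientation <- ifelse(rv$orientation == "+", "-", "+")
        bwd <- scoreDir(rv)
        chosen <- if (bwd$conc > fwd$conc) bwd else fwd
        concordant <- concordant + chosen$conc
        totalPairs <- totalPairs + chosen$tot
        orientOk <- orientOk + chosen$ok
        orientTot <- orientTot + nrow(p)
    }
    list(orderConcordance = if (totalPairs) concordant / totalPairs else NA,
         orientationAccuracy = if (orientTot) orientOk / orientTot else NA,
         nPlaced = length(unlist(lapply(linkagePaths(graph),
                                        function(p) p$scaffold))),
         nUnplaced = nrow(unplacedScaffolds(graph)))
}

#' Flag scaffold ends with collapsed-repeat coverage
#'
#' A scaffold end is excluded from linking when the log2 ratio of the mean
#' depth over its outermost \code{edgeSpan} bp to the genome-wide median
#' exceeds \code{log2Cut} (strict inequality), the signature of a
#' collapsed repeat at the scaffold edge.
#'
#' @param track A \linkS4class{DepthWindowTrack} over scaffolds.
#' @param edgeSpan Edge span in bp (default 5000).
#' @param log2Cut Exclusion threshold on the log2 ratio (default 0.5).
#' @return data.frame \code{scaffold}, \code{end} ("start"/"end"),
#'   \code{log2_ratio}, \code{excluded}.
#' @export
flagCollapsedEdges <- function(track, edgeSpan = 5000L, log2Cut = 0.5) {
    w <- depthWindows(track)
    med <- medianDepth(track)
    out <- list()
    for (s in unique(as.character(seqnames(w)))) {
        ws <- w[as.character(seqnames(w)) == s]
        ws <- ws[order(start(ws))]
        L <- max(end(ws))
        for (side in c("start", "end")) {
            sel <- if (side == "start") start(ws) <= edgeSpan
                   else end(ws) > L - edgeSpan
            if (!any(sel)) next
            m <- mean(mcols(ws)$depth[sel])
            lr <- log2(m / med)
            out[[length(out) + 1L]] <- data.frame(
                scaffold = s, end = side, log2_ratio = lr,
                ## strictly above the cut; epsilon guards boundary ratios
                ## (e.g. exactly sqrt(2)) against floating-point noise
                excluded = lr > log2Cut + 1e-9)
        }
    }
    do.call(rbind, out)
}
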