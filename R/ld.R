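## Linkage disequilibrium between haploid biallelic markers.

## r^2 matrix between two blocks of calls (segregants x markers, coded
## 1/0/NA). Pairwise-complete segregants per marker pair; monomorphic or
## under-observed pairs give NA. Cross products give, for each pair, the
## haplotype counts over shared non-missing segregants.
.ldMatrix <- function(X, Y = X, minShared = 4L) {
    Ux <- (X == 1L); Ux[is.na(Ux)] <- FALSE
    Vx <- !is.na(X)
    Uy <- (Y == 1L); Uy[is.na(Uy)] <- FALSE
    Vy <- !is.na(Y)
    storage.mode(Ux) <- "double"; storage.mode(Vx) <- "double"
    storage.mode(Uy) <- "double"; storage.mode(Vy) <- "double"
    n <- crossprod(Vx, Vy)
    nA <- crossprod(Ux, Vy)   # A at marker i, observed at j
    nB <- crossprod(Vx, Uy)
    nAB <- crossprod(Ux, Uy)
    pA <- nA / n; pB <- nB / n; pAB <- nAB / n
    D <- pAB - pA * pB
    den <- pA * (1 - pA) * pB * (1 - pB)
    r2 <- D * D / den
    r2[den <= 0 | n < minShared] <- NA_real_
    r2
}

#' Pairwise linkage disequilibrium (r-squared) between markers
#'
#' Computes LD in units of r^2 between marker pairs over the segregants
#' non-missing at both markers:
#' r^2 = (p_AB - p_A p_B)^2 / (p_A (1 - p_A) p_B (1 - p_B)).
#' Pairs where either marker is monomorphic among the shared segregants
#' (or fewer than \code{minShared} shared calls exist) are skipped and
#' reported in the \code{"skipped"} attribute.
#'
#' @param gm A \linkS4class{GenotypeMatrix}.
#' @param pairs \code{"within"} (same-scaffold pairs), \code{"between"}
#'   (cross-scaffold pairs), \code{"all"}, or a two-column integer matrix
#'   of marker indices.
#' @param minShared Minimum shared non-missing segregants per pair.
#' @return data.frame \code{marker_i}, \code{marker_j}, \code{r2},
#'   \code{same_scaffold}, \code{distance_bp} (NA across scaffolds),
#'   \code{scaffold} (for within-scaffold pairs), with skipped pairs in
#'   \code{attr(, "skipped")}.
#' @export
computePairwiseLD <- function(gm, pairs = "within", minShared = 4L) {
    calls <- genotypeCalls(gm)
    info <- markerInfo(gm)
    p <- ncol(calls)
    if (is.character(pairs)) {
        pairs <- match.arg(pairs, c("within", "between", "all"))
        idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
        same <- info$scaffold[idx[, 1L]] == info$scaffold[idx[, 2L]]
        idx <- switch(pairs,
                      within = idx[same, , drop = FALSE],
                      between = idx[!same, , drop = FALSE],
                      all = idx)
    } else idx <- pairs
    r2all <- .ldMatrix(calls, minShared = minShared)
    r2 <- r2all[idx]
    same <- info$scaffold[idx[, 1L]] == info$scaffold[idx[, 2L]]
    out <- data.frame(
        marker_i = info$marker[idx[, 1L]],
        marker_j = info$marker[idx[, 2L]],
        r2 = r2,
        same_scaffold = same,
        distance_bp = ifelse(same,
                             abs(info$pos[idx[, 1L]] - info$pos[idx[, 2L]]),
                             NA_integer_),
        scaffold = ifelse(same, info$scaffold[idx[, 1L]], NA_character_))
    skipped <- out[is.na(out$r2), c("marker_i", "marker_j")]
    if (nrow(skipped)) skipped$reason <- "monomorphic_or_too_few_shared"
    out <- out[!is.na(out$r2), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "skipped") <- skipped
    out
}

#' Fit the exponential LD decay model r^2 = exp(-lambda d)
#'
#' Nonlinear least squares fit of the decay constant lambda to observed
#' within-scaffold (r^2, distance) pairs; lambda converts LD strength into
#' estimated physical distance. Only pairs on scaffolds of at least
#' \code{minScaffoldLength} are used (short scaffolds carry little
#' long-range distance information). The one-parameter objective is
#' minimized over log(lambda), which is deterministic for given input.
#'
#' @param pairs data.frame from \code{\link{computePairwiseLD}} (needs
#'   \code{r2}, \code{distance_bp}, \code{same_scaffold}, \code{scaffold}).
#' @param scaffoldLengths Named vector of scaffold lengths in bp (NULL to
#'   skip the length filter).
#' @param minScaffoldLength Minimum scaffold length for fitting (50 kb).
#' @param minPairs Minimum number of usable pairs (default 50).
#' @return An \linkS4class{LdDecayModel}.
#' @export
fitLdDecay <- function(pairs, scaffoldLengths = NULL,
                       minScaffoldLength = 50000L, minPairs = 50L) {
    use <- pairs[pairs$same_scaffold & !is.na(pairs$r2), , drop = FALSE]
    if (!is.null(scaffoldLengths)) {
        keep <- scaffoldLengths[use$scaffold] >= minScaffoldLength
        use <- use[keep, , drop = FALSE]
    }
    if (nrow(use) < minPairs)
        .stopf("need at least %d within-scaffold pairs, got %d", minPairs,
               nrow(use))
    d <- as.numeric(use$distance_bp)
    r2 <- use$r2
    if (all(d == 0)) .stopf("degenerate fit: all pair distances are zero")
    obj <- function(loglam) {
        lam <- exp(loglam)
        sum((r2 - exp(-lam * d))^2)
    }
    opt <- stats::optimize(obj, interval = c(log(1e-10), log(1)),
                           tol = 1e-12)
    lambda <- exp(opt$minimum)
    new("LdDecayModel", lambda = lambda, fitResidual = opt$objective,
        nPairsUsed = nrow(use))
}

#' Estimated physical gap from observed LD
#'
#' Inverts the decay model: d = -ln(r^2) / lambda. An r^2 of zero maps to
#' the infinite-distance sentinel \code{Inf}.
#'
#' @param r2 Observed r^2 in [0, 1].
#' @param model An \linkS4class{LdDecayModel}.
#' @return Estimated distance in bp.
#' @export
estimateGap <- function(r2, model) {
    if (any(r2 < 0 | r2 > 1)) .stopf("r2 must lie in [0, 1]")
    ifelse(r2 == 0, Inf, -log(r2) / ldLambda(model))
}

#' Binned empirical LD decay constant
#'
#' Model-free check on \code{\link{fitLdDecay}}: bins within-scaffold r^2
#' by distance, then regresses log mean r^2 on bin midpoint; minus the
#' slope estimates the decay constant.
#'
#' @param pairs data.frame from \code{\link{computePairwiseLD}}.
#' @param binWidth Distance bin width in bp.
#' @param minMeanR2 Bins with mean r^2 below this are dropped (they are
#'   dominated by the finite-sample LD floor).
#' @return Estimated decay constant (per bp).
#' @export
binnedDecayConstant <- function(pairs, binWidth = 10000L,
                                minMeanR2 = 0.05) {
    use <- pairs[pairs$same_scaffold & !is.na(pairs$r2), , drop = FALSE]
    bin <- floor(use$distance_bp / binWidth)
    mids <- (unique(sort(bin)) + 0.5) * binWidth
    m <- tapply(use$r2, bin, mean)
    keep <- m >= minMeanR2 & as.numeric(names(m)) >= 0
    if (sum(keep) < 3L) .stopf("too few informative distance bins")
    fit <- stats::lm(log(m[keep]) ~ mids[keep])
    -unname(stats::coef(fit)[2L])
}
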