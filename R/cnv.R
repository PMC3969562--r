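#' Median-normalized windowed log2 depth
#'
#' Normalizes per-window mean read depth by the genome-wide median over
#' unmasked windows and takes log2 of the ratio. Windows overlapping the
#' mask annotation (repeats / transposon-similar sequence) are flagged and
#' excluded from the median. Strains whose genome-wide median mapped
#' coverage is below \code{minCoverage} (default 8x) are rejected: depth
#' ratios are too noisy to call copy number below that.
#'
#' @param depth data.frame \code{chrom}, \code{start}, \code{end},
#'   \code{depth} of non-overlapping windows.
#' @param mask Optional \code{GRanges} of masked intervals.
#' @param minCoverage Minimum genome-wide median depth (fold).
#' @param log2Floor Floor for the log2 ratio of zero-coverage windows.
#' @param strain Strain label.
#' @return A \linkS4class{DepthWindowTrack}.
#' @export
windowedLog2Depth <- function(depth, mask = NULL, minCoverage = 8,
                              log2Floor = -10, strain = NA_character_) {
    need <- c("chrom", "start", "end", "depth")
    if (!all(need %in% names(depth)))
        .stopf("depth table needs columns %s", paste(need, collapse = ", "))
    gr <- GRanges(depth$chrom, IRanges(depth$start, depth$end))
    masked <- if (!is.null(mask) && length(mask))
        IRanges::overlapsAny(gr, mask) else rep(FALSE, length(gr))
    med <- stats::median(depth$depth[!masked])
    if (!is.finite(med) || med < minCoverage)
        .stopf("strain excluded: genome-wide median coverage %.2fx is below %gx",
               med, minCoverage)
    normalized <- depth$depth / med
    l2 <- ifelse(normalized > 0, pmax(log2(normalized), log2Floor),
                 log2Floor)
    mcols(gr) <- DataFrame(depth = depth$depth, normalized = normalized,
                           log2_ratio = l2, masked = masked)
    new("DepthWindowTrack", windows = gr, medianDepth = med,
        strain = as.character(strain))
}

#' Segment copy-number-variable regions across strains
#'
#' Per strain, maximal runs of at least \code{minRun} consecutive unmasked
#' windows with |log2 ratio| at or above \code{log2Threshold} become gain
#' or loss calls (masked windows break runs and never enter calls). The
#' inter-strain variable-region union collects windows covered by a call
#' in at least one strain where at least two strains differ in call state,
#' so copy-number changes shared identically by every strain are not
#' "variation between strains".
#'
#' @param tracks Named list of \linkS4class{DepthWindowTrack} over
#'   identical windows (at least 2 strains).
#' @param log2Threshold Call threshold on |log2 ratio| (default 0.58,
#'   about a 1.5-fold change).
#' @param minRun Minimum run length in windows (default 3).
#' @return List: \code{calls} (data.frame \code{strain}, \code{chrom},
#'   \code{start}, \code{end}, \code{direction}, \code{mean_log2},
#'   \code{n_windows}), \code{variableRegions} (\code{GRanges}),
#'   \code{totalAffected} (bp).
#' @export
segmentCnv <- function(tracks, log2Threshold = 0.58, minRun = 3L) {
    if (length(tracks) < 2L) .stopf("need tracks for at least 2 strains")
    if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
        names(tracks) <- vapply(tracks, function(t) t@strain, "")
    tracks <- tracks[order(names(tracks))]  # strain-order invariance
    ref <- depthWindows(tracks[[1L]])
    key <- paste0(seqnames(ref), ":", start(ref))
    for (t in tracks[-1L]) {
        w <- depthWindows(t)
        if (!identical(paste0(seqnames(w), ":", start(w)), key))
            .stopf("tracks must share identical windows")
    }
    nW <- length(ref)
    state <- matrix("neutral", nW, length(tracks),
                    dimnames = list(NULL, names(tracks)))
    inCall <- matrix(FALSE, nW, length(tracks))
    calls <- list()
    chrom <- as.character(seqnames(ref))
    for (si in seq_along(tracks)) {
        w <- depthWindows(tracks[[si]])
        l2 <- mcols(w)$log2_ratio
        ok <- !mcols(w)$masked & abs(l2) >= log2Threshold
        for (ch in unique(chrom)) {
            ix <- which(chrom == ch)
            dir <- ifelse(ok[ix], ifelse(l2[ix] > 0, "gain", "loss"), "none")
            r <- rle(dir)
            endsR <- cumsum(r$lengths); startsR <- endsR - r$lengths + 1L
            for (g in which(r$values != "none" & r$lengths >= minRun)) {
                win <- ix[startsR[g]:endsR[g]]
                state[win, si] <- r$values[g]
                inCall[win, si] <- TRUE
                calls[[length(calls) + 1L]] <- data.frame(
                    strain = names(tracks)[si], chrom = ch,
                    start = min(start(w)[win]), end = max(end(w)[win]),
                    direction = r$values[g],
                    mean_log2 = mean(l2[win]),
                    n_windows = length(win))
            }
        }
    }
    calls <- if (length(calls)) do.call(rbind, calls) else
        data.frame(strain = character(), chrom = character(),
                   start = integer(), end = integer(),
                   direction = character(), mean_log2 = numeric(),
                   n_windows = integer())
    anyCall <- rowSums(inCall) > 0L
    differs <- apply(state, 1L, function(s) length(unique(s)) > 1L)
    variable <- anyCall & differs
    vr <- GenomicRanges::reduce(ref[variable])
    list(calls = calls, variableRegions = vr,
         totalAffected = sum(width(vr)))
}

#' Aggregate gene-family copy number from read depth
#'
#' Estimates the total copy number of a gene family as the sum over member
#' loci of mean unmasked normalized depth times the reference copy count
#' at that locus. Aggregating depth across close paralogs sidesteps
#' read-mapping ambiguity between family members.
#'
#' @param track A \linkS4class{DepthWindowTrack}.
#' @param members \code{GRanges} of family member loci.
#' @param refCopies Reference copy count per member locus (recycled).
#' @return Estimated family copy number (non-negative real).
#' @export
geneFamilyCopyNumber <- function(track, members, refCopies = 1) {
    refCopies <- rep_len(refCopies, length(members))
    w <- depthWindows(track)
    est <- 0
    for (i in seq_along(members)) {
        sel <- IRanges::overlapsAny(w, members[i]) & !mcols(w)$masked
        m <- if (any(sel)) mean(mcols(w)$normalized[sel]) else 0
        est <- est + m * refCopies[i]
    }
    est
}

#' Subtelomeric enrichment of copy-number variation
#'
#' Fractions of subtelomeric versus core (non-subtelomeric) nucleotide
#' positions that fall inside the variable-region union, their fold ratio,
#' and a two-proportion test on the position counts. Positions along a
#' chromosome are strongly autocorrelated, so the test treats each
#' position as independent and its p-value is anti-conservative; it is
#' reported as a summary, not a calibrated significance level.
#'
#' @param variableRegions \code{GRanges} union of variable regions.
#' @param genome An \linkS4class{AnnotatedGenome} (supplies chromosome
#'   lengths and the subtelomere span).
#' @return List: \code{fraction_subtelomeric}, \code{fraction_core},
#'   \code{fold} (\code{Inf} when the core fraction is 0 and the
#'   subtelomeric fraction positive), \code{p}.
#' @export
subtelomericEnrichment <- function(variableRegions, genome) {
    st <- subtelomeres(genome)
    lens <- width(genomeSequences(genome))
    total <- sum(lens)
    S <- sum(width(st))
    C <- total - S
    inSub <- sum(width(GenomicRanges::intersect(variableRegions, st)))
    inAll <- sum(width(GenomicRanges::reduce(variableRegions)))
    inCore <- inAll - inSub
    fs <- inSub / S
    fc <- if (C > 0) inCore / C else NA_real_
    fold <- if (is.na(fc)) NA_real_
            else if (fc == 0) { if (fs > 0) Inf else NA_real_ }
            else fs / fc
    p <- tryCatch(stats::prop.test(c(inSub, inCore), c(S, C))$p.value,
                  error = function(e) NA_real_, warning = function(w) {
                      suppressWarnings(
                          stats::prop.test(c(inSub, inCore), c(S, C))$p.value)
                  })
    list(fraction_subtelomeric = fs, fraction_core = fc, fold = fold,
         p = p)
}
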