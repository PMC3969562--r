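#' Simulate a windowed read-depth track
#'
#' Emits mean read depth in non-overlapping windows tiling the reference.
#' The expected depth of a window is \code{meanDepth} times its local copy
#' number (fractional for windows straddling a copy-number boundary).
#' Windows overlapping repeat annotation are inflated by
#' \code{repeatInflation} (emulating reads from collapsed repeats piling
#' onto one locus) and flagged masked. With \code{noise = 0} depths are
#' exact expectations; otherwise per-window read counts are drawn from a
#' negative binomial with variance \code{mu + noise * mu^2} (Poisson in
#' the small-noise limit) assuming \code{readLength}-bp reads.
#'
#' @param ref An \linkS4class{AnnotatedGenome}.
#' @param copyNumbers Optional data.frame \code{chrom}, \code{start},
#'   \code{end}, \code{copies}; copy number defaults to 1 elsewhere.
#' @param meanDepth Haploid mean coverage (fold).
#' @param window Window size in bp (default 500).
#' @param noise Overdispersion of read counts (0 = deterministic).
#' @param readLength Read length used to convert depth to counts.
#' @param repeatInflation Depth multiplier for repeat-overlapping windows.
#' @param strain Strain label stored in the track.
#' @param seed Integer seed.
#' @return A \linkS4class{DepthWindowTrack} (median-normalized; see
#'   \code{\link{windowedLog2Depth}}).
#' @export
simulateCoverage <- function(ref, copyNumbers = NULL, meanDepth = 30,
                             window = 500L, noise = 0.01,
                             readLength = 100L, repeatInflation = 2,
                             strain = NA_character_, seed = NULL) {
    if (window <= 0L) .stopf("window must be positive")
    seqs <- genomeSequences(ref)
    .withSeed(seed, {
        depthDf <- lapply(seq_along(seqs), function(i) {
            L <- width(seqs)[i]
            chrom <- names(seqs)[i]
            starts <- seq.int(1L, L, by = window)
            ends <- pmin(starts + window - 1L, L)
            cn <- rep(1, length(starts))
            if (!is.null(copyNumbers)) {
                cnc <- copyNumbers[copyNumbers$chrom == chrom, ,
                                   drop = FALSE]
                for (r in seq_len(nrow(cnc))) {
                    ov <- pmin(ends, cnc$end[r]) -
                        pmax(starts, cnc$start[r]) + 1L
                    ov <- pmax(ov, 0L) / (ends - starts + 1L)
                    cn <- cn + ov * (cnc$copies[r] - 1)
                }
            }
            mu <- meanDepth * cn
            data.frame(chrom = chrom, start = starts, end = ends,
                       mu = mu)
        })
        depthDf <- do.call(rbind, depthDf)
        gr <- GRanges(depthDf$chrom, IRanges(depthDf$start, depthDf$end))
        reps <- repeatAnnotation(ref)
        inRepeat <- if (length(reps)) IRanges::overlapsAny(gr, reps)
                    else rep(FALSE, length(gr))
        depthDf$mu[inRepeat] <- depthDf$mu[inRepeat] * repeatInflation
        if (noise > 0) {
            w <- depthDf$end - depthDf$start + 1L
            muReads <- depthDf$mu * w / readLength
            reads <- ifelse(muReads > 0,
                            stats::rnbinom(nrow(depthDf), mu = muReads,
                                           size = 1 / noise),
                            0)
            depthDf$depth <- reads * readLength / w
        } else depthDf$depth <- depthDf$mu
        depthDf$mu <- NULL
        windowedLog2Depth(depthDf, mask = reps, strain = strain)
    })
}

#' Simulate copy-number-dependent phenotypes
#'
#' Additive mode: \code{E[y] = intercept + slope * copies}. Saturating
#' mode: the copy-number effect plateaus at one copy
#' (\code{E[y] = intercept + slope * min(copies, 1)}), emulating
#' phenotypes where adding copies beyond the first confers no further
#' benefit.
#'
#' @param copies data.frame \code{strain}, \code{copies}, or a named
#'   numeric vector.
#' @param intercept,slope Linear model parameters.
#' @param saturating Use the saturating mode.
#' @param noiseSD Gaussian residual standard deviation.
#' @param seed Integer seed.
#' @return data.frame \code{strain}, \code{copies}, \code{phenotype}.
#' @export
simulatePhenotypes <- function(copies, intercept = 0, slope = 1,
                               saturating = FALSE, noiseSD = 0,
                               seed = NULL) {
    if (!is.data.frame(copies))
        copies <- data.frame(strain = names(copies),
                             copies = as.numeric(copies))
    .withSeed(seed, {
        eff <- if (saturating) pmin(copies$copies, 1) else copies$copies
        y <- intercept + slope * eff +
            stats::rnorm(nrow(copies), 0, noiseSD)
        data.frame(strain = copies$strain, copies = copies$copies,
                   phenotype = y)
    })
}
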