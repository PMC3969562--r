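#' Call segregant genotypes from log-likelihood ratios
#'
#' Applies the threshold rule used for segregant genotyping: call parent A
#' when LLR is greater than \code{threshold}, parent B when smaller than
#' \code{-threshold}, and missing otherwise (strict inequalities, so an
#' LLR exactly at the threshold is a no-call). Default threshold 10
#' log-likelihood units.
#'
#' @param llr data.frame with columns \code{segregant}, \code{marker},
#'   \code{scaffold}, \code{pos}, \code{llr}; one row per
#'   (segregant, marker).
#' @param threshold Positive LLR threshold (default 10).
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
callSegregantGenotypes <- function(llr, threshold = 10) {
    stopifnot(threshold > 0)
    need <- c("segregant", "marker", "scaffold", "pos", "llr")
    if (!all(need %in% names(llr)))
        .stopf("llr table must have columns %s",
               paste(need, collapse = ", "))
    if (anyDuplicated(llr[, c("segregant", "marker")]))
        .stopf("duplicate (segregant, marker) rows in LLR table")
    m <- unique(llr[, c("marker", "scaffold", "pos")])
    m <- m[order(m$scaffold, m$pos, m$marker), , drop = FALSE]
    segs <- sort(unique(llr$segregant))
    calls <- matrix(NA_integer_, length(segs), nrow(m),
                    dimnames = list(segs, m$marker))
    val <- ifelse(llr$llr > threshold, 1L,
                  ifelse(llr$llr < -threshold, 0L, NA_integer_))
    calls[cbind(match(llr$segregant, segs), match(llr$marker, m$marker))] <-
        val
    new("GenotypeMatrix", calls = calls,
        markers = DataFrame(marker = m$marker, scaffold = m$scaffold,
                            pos = m$pos))
}

#' Filter segregants with excess intermediate calls
#'
#' Segregants whose fraction of missing (intermediate-likelihood) calls
#' exceeds \code{maxIntermediateFraction} are removed; such genome-wide
#' intermediate signal is the signature of diploid or contaminated
#' segregant DNA.
#'
#' @param gm A \linkS4class{GenotypeMatrix}.
#' @param maxIntermediateFraction Removal cutoff (strictly above).
#' @return List: \code{genotypes} (filtered matrix), \code{excluded}
#'   (segregant ids), \code{retained} (count).
#' @export
filterSegregants <- function(gm, maxIntermediateFraction = 0.2) {
    calls <- genotypeCalls(gm)
    frac <- rowMeans(is.na(calls))
    bad <- frac > maxIntermediateFraction
    out <- new("GenotypeMatrix", calls = calls[!bad, , drop = FALSE],
               markers = markerInfo(gm))
    list(genotypes = out, excluded = rownames(calls)[bad],
         retained = sum(!bad))
}

#' Call a haploid indel genotype from a log-likelihood ratio
#'
#' Threshold rule for indel genotypes (default 5.3 log-likelihood units,
#' strict inequalities): \code{"alt"} when LLR > threshold, \code{"ref"}
#' when LLR < -threshold, \code{NA} otherwise.
#'
#' @param llr Numeric vector of log-likelihood ratios (alt over ref).
#' @param threshold Positive threshold (default 5.3).
#' @return Character vector in \{"alt", "ref", NA\}.
#' @export
callIndelGenotype <- function(llr, threshold = 5.3) {
    stopifnot(threshold > 0)
    ifelse(llr > threshold, "alt",
           ifelse(llr < -threshold, "ref", NA_character_))
}
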