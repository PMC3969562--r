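#' Polarize alleles against an outgroup
#'
#' The ancestral allele of a biallelic site is taken to be the outgroup
#' allele when it matches one of the two ingroup alleles; sites where the
#' outgroup carries a third allele (or no call) are flagged unpolarized
#' and excluded from frequency spectra.
#'
#' @param variants data.frame with \code{variant_id}, \code{ref},
#'   \code{alt}.
#' @param carriers Logical matrix (variants x strains), TRUE where the
#'   strain carries the alt allele.
#' @param outgroup Character vector of outgroup alleles per variant.
#' @return data.frame \code{variant_id}, \code{ancestral},
#'   \code{derived}, \code{derived_count}, \code{n_strains},
#'   \code{polarized}.
#' @export
polarizeAlleles <- function(variants, carriers, outgroup) {
    n <- ncol(carriers)
    altCount <- rowSums(carriers)
    anc <- ifelse(outgroup == variants$ref, variants$ref,
                  ifelse(outgroup == variants$alt, variants$alt,
                         NA_character_))
    der <- ifelse(is.na(anc), NA_character_,
                  ifelse(anc == variants$ref, variants$alt, variants$ref))
    dcount <- ifelse(is.na(anc), NA_integer_,
                     ifelse(anc == variants$ref, altCount, n - altCount))
    data.frame(variant_id = variants$variant_id, ancestral = anc,
               derived = der, derived_count = as.integer(dcount),
               n_strains = n, polarized = !is.na(anc))
}

#' Derived allele frequency spectrum by effect class
#'
#' Tabulates polarized variants by derived allele count and effect class.
#' Row sums per class equal the number of polarized variants in that
#' class.
#'
#' @param polarized Output of \code{\link{polarizeAlleles}}.
#' @param effectClass Character vector of class labels per variant.
#' @return Matrix of counts, rows = derived count 1..n, columns = class.
#' @export
dafSpectrum <- function(polarized, effectClass) {
    keep <- polarized$polarized & polarized$derived_count >= 1L
    n <- polarized$n_strains[1L]
    tab <- table(factor(polarized$derived_count[keep], levels = 1:n),
                 effectClass[keep])
    m <- matrix(tab, nrow = n,
                dimnames = list(derived_count = 1:n,
                                class = colnames(tab)))
    m
}

#' Nonsynonymous/synonymous polymorphism ratios for two gene sets
#'
#' Pools segregating nonsynonymous and synonymous SNP counts within each
#' gene set, reports the pN/pS ratios, and compares the two sets with a
#' two-sided Fisher exact test on the 2x2 count table. An elevated ratio
#' indicates relaxed purifying selection on that gene set.
#'
#' @param snpEffects data.frame with \code{orf_id} and \code{effect}
#'   (counting \code{"nonsynonymous"} vs \code{"synonymous"} rows).
#' @param genesA,genesB Character vectors of ORF ids.
#' @return List: \code{setA}, \code{setB} (each \code{n_nonsyn},
#'   \code{n_syn}, \code{ratio}), \code{p}.
#' @export
pnPs <- function(snpEffects, genesA, genesB) {
    count <- function(genes) {
        sel <- snpEffects$orf_id %in% genes
        c(n = sum(sel & snpEffects$effect == "nonsynonymous"),
          s = sum(sel & snpEffects$effect == "synonymous"))
    }
    a <- count(genesA); b <- count(genesB)
    tab <- matrix(c(a["n"], a["s"], b["n"], b["s"]), nrow = 2L)
    p <- stats::fisher.test(tab)$p.value
    list(setA = list(n_nonsyn = unname(a["n"]), n_syn = unname(a["s"]),
                     ratio = unname(a["n"] / a["s"])),
         setB = list(n_nonsyn = unname(b["n"]), n_syn = unname(b["s"]),
                     ratio = unname(b["n"] / b["s"])),
         p = p)
}

#' Count paralogs per gene from protein similarity hits
#'
#' A paralog is another gene whose protein similarity hit is significant
#' and covers at least \code{minCoverage} of the query protein length.
#' The similarity engine is pluggable: any table of hits with
#' \code{query}, \code{subject}, \code{significant}, \code{coverage}
#' columns qualifies (see \code{\link{proteinSimilarityHits}} for the
#' built-in engine).
#'
#' @param hits data.frame of similarity hits.
#' @param genes Character vector of all gene ids (genes without hits get
#'   a count of 0).
#' @param minCoverage Minimum query coverage (default 0.8).
#' @return Named integer vector of paralog counts.
#' @export
countParalogs <- function(hits, genes, minCoverage = 0.8) {
    counts <- stats::setNames(integer(length(genes)), genes)
    keep <- hits$significant & hits$coverage >= minCoverage &
        hits$query != hits$subject
    if (any(keep)) {
        t <- table(factor(hits$query[keep], levels = genes))
        counts[names(t)] <- as.integer(t)
    }
    counts
}

#' Built-in protein similarity engine
#'
#' All-against-all local protein alignment (BLOSUM62,
#' \code{Biostrings::pairwiseAlignment}); a hit is significant when the
#' aligned identity reaches \code{minIdentity}. Coverage is the aligned
#' fraction of the query length. Quadratic in the number of proteins, so
#' intended for moderate gene sets.
#'
#' @param proteins An \code{AAStringSet} with unique names.
#' @param minIdentity Identity threshold for significance (default 0.9).
#' @return data.frame \code{query}, \code{subject}, \code{identity},
#'   \code{coverage}, \code{significant}.
#' @export
proteinSimilarityHits <- function(proteins, minIdentity = 0.9) {
    nm <- names(proteins)
    out <- list()
    for (i in seq_along(proteins)) for (j in seq_along(proteins)) {
        if (i == j) next
        aln <- Biostrings::pairwiseAlignment(
            proteins[[i]], proteins[[j]], type = "local",
            substitutionMatrix = "BLOSUM62", gapOpening = 10,
            gapExtension = 0.5)
        alnLen <- Biostrings::nchar(Biostrings::pattern(aln))
        cov <- alnLen / length(proteins[[i]])
        ident <- Biostrings::pid(aln) / 100
        out[[length(out) + 1L]] <- data.frame(
            query = nm[i], subject = nm[j], identity = ident,
            coverage = cov,
            significant = ident >= minIdentity & alnLen >= 20L)
    }
    do.call(rbind, out)
}
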