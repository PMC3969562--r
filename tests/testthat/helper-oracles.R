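## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths.

## LD r^2 by direct haplotype counting over shared non-missing segregants.
r2CountOracle <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    pA <- mean(x == 1L)
    pB <- mean(y == 1L)
    pAB <- mean(x == 1L & y == 1L)
    den <- pA * (1 - pA) * pB * (1 - pB)
    if (den == 0) return(NA_real_)
    (pAB - pA * pB)^2 / den
}

## Two-sided Fisher exact p by hypergeometric enumeration over all tables
## with the observed margins (same support-comparison convention as
## stats::fisher.test: probabilities <= observed * (1 + 1e-7) count).
fisherEnumOracle <- function(tab) {
    m <- sum(tab[1L, ]); n <- sum(tab[2L, ]); k <- sum(tab[, 1L])
    lo <- max(0L, k - n); hi <- min(k, m)
    support <- lo:hi
    d <- dhyper(support, m, n, k)
    d0 <- dhyper(tab[1L, 1L], m, n, k)
    sum(d[d <= d0 * (1 + 1e-7)])
}

## Exact binomial upper tail P(X >= k).
binomTailOracle <- function(k, n, p) {
    sum(dbinom(k:n, n, p))
}

## Effect of a SNP by whole-ORF re-translation (independent of the
## codon-arithmetic path): extract the ORF sequence with and without the
## substitution, translate both, compare amino acids.
translationEffectOracle <- function(genome, chrom, pos, alt, orf) {
    seqs <- genomeSequences(genome)
    refSeq <- Biostrings::subseq(seqs[[chrom]], start(orf), end(orf))
    chars <- strsplit(as.character(seqs[[chrom]]), "", fixed = TRUE)[[1L]]
    chars[pos] <- alt
    altSeq <- Biostrings::DNAString(
        paste(chars[start(orf):end(orf)], collapse = ""))
    if (as.character(strand(orf)) == "-") {
        refSeq <- Biostrings::reverseComplement(refSeq)
        altSeq <- Biostrings::reverseComplement(altSeq)
    }
    aaRef <- as.character(Biostrings::translate(refSeq,
                                                no.init.codon = TRUE,
                                                if.fuzzy.codon = "X"))
    aaAlt <- as.character(Biostrings::translate(altSeq,
                                                no.init.codon = TRUE,
                                                if.fuzzy.codon = "X"))
    if (aaRef == aaAlt) return("synonymous")
    i <- which(strsplit(aaRef, "")[[1L]] != strsplit(aaAlt, "")[[1L]])[1L]
    r <- substr(aaRef, i, i); a <- substr(aaAlt, i, i)
    if (a == "*") "stop_gain" else if (r == "*") "stop_loss"
    else "nonsynonymous"
}

## All anchors at which applying the indel yields the same edited string;
## exhaustive enumeration over every position in the context.
equivalentRegionOracle <- function(sequence, pos, ref, alt) {
    s <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    L <- length(s)
    applyEdit <- function(anchor) {
        if (nchar(alt)) {
            paste(c(s[seq_len(anchor)], alt,
                    if (anchor < L) s[(anchor + 1L):L]), collapse = "")
        } else {
            k <- nchar(ref)
            if (anchor + k > L) return(NA_character_)
            paste(s[-((anchor + 1L):(anchor + k))], collapse = "")
        }
    }
    target <- applyEdit(pos)
    maxAnchor <- if (nchar(alt)) L else L - nchar(ref)
    anchors <- Filter(function(a) {
        e <- applyEdit(a)
        !is.na(e) && e == target
    }, 0:maxAnchor)
    anchors <- unlist(anchors)
    if (nchar(ref)) c(min(anchors) + 1L, max(anchors) + nchar(ref))
    else c(max(1L, min(anchors)), max(anchors))
}

## The unrooted split {A,B} | {C,D} induced by a 4-taxon tree.
quartetSplit <- function(tree) {
    tips <- sort(tree$tip.label)
    ## the cherry containing the first tip defines the split
    pairs <- combn(tips, 2L, simplify = FALSE)
    for (p in pairs) {
        others <- setdiff(tips, p)
        d <- ape::cophenetic.phylo(tree)
        ## four-point condition: p is a cherry iff
        ## d(p1,p2) + d(o1,o2) <= min of the two crossing sums
        s1 <- d[p[1L], p[2L]] + d[others[1L], others[2L]]
        s2 <- d[p[1L], others[1L]] + d[p[2L], others[2L]]
        s3 <- d[p[1L], others[2L]] + d[p[2L], others[1L]]
        if (s1 < min(s2, s3) - 1e-9) return(paste(sort(p), collapse = ","))
    }
    NA_character_
}

## Least-squares additive fit over the 3 unrooted 4-taxon topologies:
## returns the split of the best-fitting topology.
bruteForceQuartetOracle <- function(dm) {
    tips <- rownames(dm)
    splits <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L))
    best <- NULL; bestRss <- Inf
    for (sp in splits) {
        a <- tips[sp]; b <- setdiff(tips, a)
        ## topology ((a1,a2),(b1,b2)): path lengths parameterized by 5
        ## branch lengths x = (ea1, ea2, eb1, eb2, em)
        A <- matrix(0, 6L, 5L)
        y <- numeric(6L)
        pairs <- combn(tips, 2L, simplify = FALSE)
        for (i in seq_along(pairs)) {
            p <- pairs[[i]]
            y[i] <- dm[p[1L], p[2L]]
            for (t in p) {
                j <- match(t, c(a, b))
                A[i, j] <- 1
            }
            crosses <- !(all(p %in% a) || all(p %in% b))
            if (crosses) A[i, 5L] <- 1
        }
        x <- stats::coef(stats::lm.fit(A, y))
        x[is.na(x)] <- 0
        rss <- sum((y - A %*% x)^2)
        if (rss < bestRss) { bestRss <- rss; best <- paste(sort(a),
                                                          collapse = ",") }
    }
    best
}
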