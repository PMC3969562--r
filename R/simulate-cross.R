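#' Advanced intercross design
#'
#' Bundles the design parameters of a two-parent advanced intercross
#' (default: an F12 line of 192 segregants, the design used for
#' linkage-assisted scaffolding of yeast assemblies). Recombination is
#' modelled as Poisson crossovers accumulating linearly over generations
#' (expected crossovers per chromosome per segregant =
#' \code{generations * mapDensity}); segregant haplotypes alternate parent
#' at each crossover.
#'
#' @param generations Number of intercross generations (default 12).
#' @param nSegregants Total segregants, including contaminants.
#' @param mapDensity Crossovers per chromosome per meiosis (default 1).
#' @param genotypingError Probability a marker emission has flipped sign.
#' @param missingRate Probability a marker emits an intermediate
#'   (uninformative) likelihood.
#' @param nContaminants Segregants emulating diploid/contaminated DNA:
#'   they emit intermediate likelihoods at about half of all markers.
#' @return A list of class \code{crossDesign}.
#' @export
crossDesign <- function(generations = 12L, nSegregants = 192L,
                        mapDensity = 1.0, genotypingError = 0.002,
                        missingRate = 0.02, nContaminants = 20L) {
    stopifnot(generations >= 1L, nSegregants >= 1L,
              genotypingError >= 0, genotypingError <= 1,
              missingRate >= 0, missingRate <= 1,
              nContaminants >= 0L, nContaminants <= nSegregants)
    structure(list(generations = as.integer(generations),
                   nSegregants = as.integer(nSegregants),
                   mapDensity = mapDensity,
                   genotypingError = genotypingError,
                   missingRate = missingRate,
                   nContaminants = as.integer(nContaminants)),
              class = "crossDesign")
}

#' Markers distinguishing two parents of a cross
#'
#' SNP events carried by exactly one of the two parent strains, i.e. the
#' sites at which segregants are informative.
#'
#' @param truth The \code{truth} element from \code{simulatePopulation}.
#' @param parents Character vector of two strain labels.
#' @return data.frame with \code{chrom}, \code{pos}, sorted.
#' @export
crossMarkers <- function(truth, parents) {
    stopifnot(length(parents) == 2L)
    sel <- truth$events$type == "snp" &
        (truth$carriers[, parents[1L]] != truth$carriers[, parents[2L]])
    m <- data.frame(chrom = truth$events$chrom[sel],
                    pos = truth$events$start[sel])
    m <- unique(m[order(m$chrom, m$pos), , drop = FALSE])
    rownames(m) <- NULL
    m
}

#' Simulate intercross segregants and their genotype likelihoods
#'
#' Simulates haploid segregant genomes of a two-parent advanced intercross
#' at the given marker positions, then emits per-marker log-likelihood
#' ratios (LLR, parent A over parent B): the true allele gives an LLR of
#' matching sign drawn from N(+/-18, 4); genotyping errors flip the sign;
#' missing emissions and contaminant segregants draw intermediate values
#' from N(0, 3), so they fall inside the no-call band of the downstream
#' threshold rule.
#'
#' @param markers data.frame with \code{chrom} (or \code{scaffold}) and
#'   \code{pos}; every chromosome present must carry at least one marker.
#' @param chromLengths Named vector of chromosome/scaffold lengths in bp.
#' @param design A \code{\link{crossDesign}}.
#' @param seed Integer seed.
#' @return List: \code{llr} (data.frame \code{segregant}, \code{marker},
#'   \code{scaffold}, \code{pos}, \code{llr}), \code{genotypes} (true
#'   \linkS4class{GenotypeMatrix}), \code{contaminants} (ids).
#' @export
simulateIntercross <- function(markers, chromLengths,
                               design = crossDesign(), seed = NULL) {
    if (design$nSegregants < 1L) .stopf("nSegregants must be >= 1")
    chromCol <- if ("scaffold" %in% names(markers)) "scaffold" else "chrom"
    markers <- markers[order(markers[[chromCol]], markers$pos), ,
                       drop = FALSE]
    chroms <- unique(markers[[chromCol]])
    if (!all(chroms %in% names(chromLengths)))
        .stopf("chromLengths missing entries for some marker chromosomes")
    if (any(!names(chromLengths) %in% chroms))
        chroms <- chroms  # chromosomes without markers are uninformative
    .withSeed(seed, {
        n <- design$nSegregants
        segIds <- sprintf("seg%03d", seq_len(n))
        contaminants <- if (design$nContaminants > 0L)
            segIds[(n - design$nContaminants + 1L):n] else character()
        markerIds <- sprintf("m%05d", seq_len(nrow(markers)))
        calls <- matrix(NA_integer_, n, nrow(markers),
                        dimnames = list(segIds, markerIds))
        xoverRate <- design$generations * design$mapDensity
        for (ch in chroms) {
            idx <- which(markers[[chromCol]] == ch)
            pos <- markers$pos[idx]
            L <- chromLengths[[ch]]
            for (s in seq_len(n)) {
                nX <- stats::rpois(1L, xoverRate)
                parent0 <- stats::runif(1L) < 0.5
                if (nX == 0L) {
                    allele <- rep(parent0, length(pos))
                } else {
                    bp <- sort(stats::runif(nX, 0, L))
                    nBefore <- findInterval(pos, bp)
                    allele <- xor(parent0, nBefore %% 2L == 1L)
                }
                calls[s, idx] <- as.integer(allele)
            }
        }
        ## emissions
        nm <- length(calls)
        mu <- ifelse(calls == 1L, 18, -18)
        err <- matrix(stats::runif(nm) < design$genotypingError,
                      nrow(calls))
        mu[err] <- -mu[err]
        llr <- mu + stats::rnorm(nm, 0, 4)
        interm <- matrix(stats::runif(nm) < design$missingRate, nrow(calls))
        if (length(contaminants)) {
            contRows <- rownames(calls) %in% contaminants
            interm[contRows, ] <- interm[contRows, ] |
                matrix(stats::runif(sum(contRows) * ncol(calls)) < 0.5,
                       sum(contRows))
        }
        llr[interm] <- stats::rnorm(sum(interm), 0, 3)

        llrDf <- data.frame(
            segregant = rep(segIds, times = ncol(calls)),
            marker = rep(markerIds, each = nrow(calls)),
            scaffold = rep(markers[[chromCol]], each = nrow(calls)),
            pos = rep(markers$pos, each = nrow(calls)),
            llr = as.vector(llr))
        gm <- new("GenotypeMatrix", calls = calls,
                  markers = DataFrame(marker = markerIds,
                                      scaffold = markers[[chromCol]],
                                      pos = markers$pos))
        list(llr = llrDf, genotypes = gm, contaminants = contaminants)
    })
}

#' Fragment a genome into shuffled, randomly oriented scaffolds
#'
#' Partitions each chromosome into contiguous fragments with sizes around
#' \code{n50Target}, reverse-complements about half of them, shuffles the
#' labels, and returns the scaffolds together with a truth placement table
#' from which the original chromosomes can be reconstructed exactly.
#'
#' @param seqs A \code{DNAStringSet} (or \code{AnnotatedGenome}).
#' @param n50Target Target fragment size in bp (must be less than or equal
#'   to the chromosome length; a chromosome-sized target yields one
#'   scaffold).
#' @param minSize Minimum fragment size in bp.
#' @param seed Integer seed.
#' @return List: \code{scaffolds} (\code{DNAStringSet}), \code{placement}
#'   (data.frame \code{scaffold}, \code{chrom}, \code{start}, \code{end},
#'   \code{strand}, \code{rank}).
#' @export
fragmentGenome <- function(seqs, n50Target, minSize = 1000L, seed = NULL) {
    if (is(seqs, "AnnotatedGenome")) seqs <- genomeSequences(seqs)
    if (minSize > n50Target) .stopf("minSize must not exceed n50Target")
    if (any(n50Target > width(seqs)))
        .stopf("n50Target exceeds a chromosome length")
    .withSeed(seed, {
        place <- list()
        for (i in seq_along(seqs)) {
            L <- width(seqs)[i]
            if (n50Target >= L) {
                cuts <- L
            } else {
                cuts <- integer()
                at <- 0L
                while (at < L) {
                    w <- max(minSize,
                             as.integer(round(stats::rnorm(1L, n50Target,
                                                           n50Target / 4))))
                    at <- min(L, at + w)
                    cuts <- c(cuts, at)
                }
                ## avoid a terminal sliver below minSize
                k <- length(cuts)
                if (k > 1L && cuts[k] - cuts[k - 1L] < minSize)
                    cuts <- cuts[-(k - 1L)]
            }
            starts <- c(1L, utils::head(cuts, -1L) + 1L)
            place[[i]] <- data.frame(chrom = names(seqs)[i],
                                     start = starts, end = cuts,
                                     rank = seq_along(cuts))
        }
        place <- do.call(rbind, place)
        nScf <- nrow(place)
        place$strand <- sample(c("+", "-"), nScf, replace = TRUE)
        whole <- place$start == 1L &
            place$end == width(seqs)[match(place$chrom, names(seqs))]
        place$strand[whole] <- "+"  # an uncut chromosome keeps identity
        labels <- sprintf("scf%03d", sample.int(nScf))
        place$scaffold <- labels
        scf <- vector("list", nScf)
        for (r in seq_len(nScf)) {
            s <- Biostrings::subseq(seqs[[place$chrom[r]]],
                                    place$start[r], place$end[r])
            if (place$strand[r] == "-")
                s <- Biostrings::reverseComplement(s)
            scf[[r]] <- s
        }
        names(scf) <- place$scaffold
        scf <- DNAStringSet(scf)[order(place$scaffold)]
        place <- place[, c("scaffold", "chrom", "start", "end", "strand",
                           "rank")]
        rownames(place) <- NULL
        list(scaffolds = scf, placement = place)
    })
}

#' Reassemble chromosomes from scaffolds and a truth placement
#'
#' Inverse of \code{\link{fragmentGenome}}; used to verify that
#' fragmentation partitions chromosomes exactly.
#' @param scaffolds \code{DNAStringSet}.
#' @param placement Placement table from \code{fragmentGenome}.
#' @return \code{DNAStringSet} of reconstructed chromosomes.
#' @export
reassembleFromPlacement <- function(scaffolds, placement) {
    out <- lapply(split(placement, placement$chrom), function(p) {
        p <- p[order(p$rank), , drop = FALSE]
        parts <- lapply(seq_len(nrow(p)), function(r) {
            s <- scaffolds[[p$scaffold[r]]]
            if (p$strand[r] == "-") s <- Biostrings::reverseComplement(s)
            as.character(s)
        })
        paste(unlist(parts), collapse = "")
    })
    DNAStringSet(unlist(out))
}

#' Re-express an LLR table in scaffold coordinates
#'
#' Recombination happens on chromosomes, so intercross emissions are
#' simulated in reference coordinates; this remaps the \code{scaffold}
#' and \code{pos} columns of an LLR table onto fragmented scaffolds using
#' a truth placement, producing the table a scaffolding run would see.
#' Markers falling outside every placed fragment are dropped.
#'
#' @param llr LLR data.frame (reference coordinates in
#'   \code{scaffold}/\code{pos}).
#' @param placement Placement table from \code{\link{fragmentGenome}}.
#' @return The remapped LLR data.frame.
#' @export
remapLlrTable <- function(llr, placement) {
    newScf <- rep(NA_character_, nrow(llr))
    newPos <- rep(NA_integer_, nrow(llr))
    for (r in seq_len(nrow(placement))) {
        p <- placement[r, ]
        sel <- llr$scaffold == p$chrom & llr$pos >= p$start &
            llr$pos <= p$end
        if (!any(sel)) next
        newScf[sel] <- p$scaffold
        newPos[sel] <- if (p$strand == "+") llr$pos[sel] - p$start + 1L
                       else p$end - llr$pos[sel] + 1L
    }
    keep <- !is.na(newScf)
    out <- llr[keep, , drop = FALSE]
    out$scaffold <- newScf[keep]
    out$pos <- newPos[keep]
    rownames(out) <- NULL
    out
}

#' Map reference-coordinate markers onto fragmented scaffolds
#'
#' @param markers data.frame with \code{chrom}, \code{pos} (reference
#'   coordinates).
#' @param placement Placement table from \code{fragmentGenome}.
#' @return data.frame \code{scaffold}, \code{pos} (scaffold-local,
#'   orientation-aware), plus the original columns as \code{chrom0},
#'   \code{pos0}.
#' @export
markersToScaffolds <- function(markers, placement) {
    out <- lapply(seq_len(nrow(markers)), function(i) {
        ch <- markers$chrom[i]; p <- markers$pos[i]
        hit <- placement[placement$chrom == ch & placement$start <= p &
                         placement$end >= p, , drop = FALSE]
        if (!nrow(hit)) return(NULL)
        hit <- hit[1L, ]
        local <- if (hit$strand == "+") p - hit$start + 1L
                 else hit$end - p + 1L
        data.frame(scaffold = hit$scaffold, pos = local, chrom0 = ch,
                   pos0 = p)
    })
    out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
    out[order(out$scaffold, out$pos), , drop = FALSE]
}
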