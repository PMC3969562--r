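#' Star phylogeny helper
#'
#' @param nTips Number of strains.
#' @param branchLength Branch length per tip, substitutions per bp.
#' @param labels Optional tip labels (default \code{s1..sn}).
#' @return An \code{ape} \code{phylo} object.
#' @export
starTree <- function(nTips, branchLength, labels = NULL) {
    tr <- ape::stree(nTips, type = "star")
    tr$edge.length <- rep(branchLength, nrow(tr$edge))
    tr$tip.label <- if (is.null(labels)) sprintf("s%d", seq_len(nTips))
                    else labels
    tr
}

#' Simulate a structured strain population from a reference genome
#'
#' Evolves strain genomes along a rooted phylogeny. Each branch receives
#' Poisson numbers of events: SNPs, short indels (1-10 bp), segment gains
#' (novel sequence insertions), segment losses (deletions), tandem
#' duplications (CNV) and loss-of-function events (premature stop SNPs or
#' frameshifting insertions planted inside eligible ORFs). Gain, loss and
#' CNV events are placed in subtelomeres with a configurable fold
#' enrichment over the core genome. Every event is recorded in a truth
#' table along with the set of carrier strains, so downstream detection
#' stages can be scored exactly.
#'
#' Purifying selection is emulated at generation time: random SNPs that
#' would introduce a premature stop codon are rejected and resampled, and
#' random frame-shifting indels inside ORFs are rejected with probability
#' \code{frameshiftRejection} (surviving in-ORF frameshifts are recorded
#' as loss-of-function truth). Targeted loss-of-function events avoid
#' essential and dubious ORFs unless \code{allowEssentialLof} is set.
#' Segment events never overlap one another or loss-of-function target
#' ORFs, so truth coordinates stay exact; an event that cannot be placed
#' raises an error reporting the locus.
#'
#' @param ref An \linkS4class{AnnotatedGenome}.
#' @param tree Rooted \code{phylo} with branch lengths in substitutions/bp.
#' @param rates Named list of per-bp-per-unit-branch-length event rates:
#'   \code{snp}, \code{indel}, \code{gain}, \code{loss}, \code{cnv},
#'   \code{lof}. Missing entries take the defaults shown in Usage.
#' @param subtelEnrichment Fold enrichment of segment gain/loss/CNV rates
#'   in subtelomeres relative to the core genome (default 40, the order of
#'   enrichment seen for subtelomeric CNV in natural yeast populations).
#' @param gainLengthRange,lossLengthRange,cnvLengthRange Segment length
#'   ranges in bp.
#' @param frameshiftRejection Probability that a proposed frame-shifting
#'   random indel inside an ORF is rejected (default 0.9).
#' @param allowEssentialLof Allow loss-of-function events in essential ORFs.
#' @param segmentPadding Minimum separation in bp between segment events
#'   (gain/loss/CNV), so each event remains an individually resolvable
#'   region downstream (default 1200).
#' @param seed Integer seed.
#' @return List with \code{genomes} (named list of \code{DNAStringSet})
#'   and \code{truth}: \code{tree}, \code{events} (one row per event),
#'   \code{carriers} (events x strains logical matrix),
#'   \code{copy_numbers}, \code{lof_events}, \code{subtel_fraction}.
#' @export
simulatePopulation <- function(ref, tree,
                               rates = list(snp = 1, indel = 0.05,
                                            gain = 4e-4, loss = 4e-4,
                                            cnv = 2e-4, lof = 2e-4),
                               subtelEnrichment = 40,
                               gainLengthRange = c(1000L, 8000L),
                               lossLengthRange = c(1000L, 8000L),
                               cnvLengthRange = c(2000L, 8000L),
                               frameshiftRejection = 0.9,
                               allowEssentialLof = FALSE,
                               segmentPadding = 1200L,
                               seed = NULL) {
    stopifnot(inherits(tree, "phylo"))
    if (length(tree$tip.label) < 2L) .stopf("tree must have >= 2 leaves")
    defaults <- list(snp = 1, indel = 0.05, gain = 4e-4, loss = 4e-4,
                     cnv = 2e-4, lof = 2e-4)
    rates <- utils::modifyList(defaults, as.list(rates))
    if (any(unlist(rates) < 0)) .stopf("rates must be >= 0")

    seqs <- genomeSequences(ref)
    ctx <- list(
        chromNames = names(seqs),
        chromLens = setNames(width(seqs), names(seqs)),
        refChars = lapply(as.character(seqs), function(s)
            strsplit(s, "", fixed = TRUE)[[1L]]),
        orfs = orfAnnotation(ref),
        stAll = subtelomeres(ref))
    ctx$G <- sum(ctx$chromLens)
    ctx$fSub <- sum(width(ctx$stAll)) / ctx$G

    .withSeed(seed, {
        env <- new.env(parent = emptyenv())
        env$events <- list()
        env$occupied <- GRanges()
        env$counter <- 0L

        nTip <- length(tree$tip.label)
        root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
        childEdges <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])

        nodeState <- vector("list", nTip + tree$Nnode)
        nodeEvents <- vector("list", nTip + tree$Nnode)
        emptyPos <- setNames(lapply(ctx$chromNames, function(x) integer()),
                             ctx$chromNames)
        nodeState[[root]] <- list(snpPos = emptyPos, lofOrfs = character())
        nodeEvents[[root]] <- character()

        queue <- root
        while (length(queue)) {
            node <- queue[1L]; queue <- queue[-1L]
            for (ei in childEdges[[as.character(node)]]) {
                child <- tree$edge[ei, 2L]
                res <- .simulateBranch(env, tree$edge.length[ei], rates,
                                       nodeState[[node]], ctx,
                                       subtelEnrichment, gainLengthRange,
                                       lossLengthRange, cnvLengthRange,
                                       frameshiftRejection,
                                       allowEssentialLof, segmentPadding)
                nodeEvents[[child]] <- c(nodeEvents[[node]], res$eventIds)
                nodeState[[child]] <- res$state
                if (child > nTip) queue <- c(queue, child)
            }
        }

        events <- .eventsToFrame(env$events)
        strains <- tree$tip.label
        carriers <- matrix(FALSE, nrow(events), nTip,
                           dimnames = list(events$event_id, strains))
        for (i in seq_len(nTip)) carriers[nodeEvents[[i]], i] <- TRUE

        genomes <- lapply(seq_len(nTip), function(i)
            .applyStrainEvents(ctx$refChars,
                               events[carriers[, i], , drop = FALSE],
                               ctx$chromNames))
        names(genomes) <- strains

        list(genomes = genomes,
             truth = list(tree = tree, events = events, carriers = carriers,
                          copy_numbers = .copyNumberTruth(events, carriers),
                          lof_events = .lofTruth(events, carriers),
                          subtel_fraction = ctx$fSub))
    })
}

.EVENT_DEFAULTS <- list(
    event_id = NA_character_, type = NA_character_, chrom = NA_character_,
    start = NA_integer_, end = NA_integer_, ref = NA_character_,
    alt = NA_character_, length = NA_integer_, subtelomeric = NA,
    lof = FALSE, lof_kind = NA_character_, orf_id = NA_character_,
    rel_pos = NA_real_, copies = NA_integer_)

.emptyEvents <- function() {
    as.data.frame(lapply(.EVENT_DEFAULTS, function(d) d[0]),
                  stringsAsFactors = FALSE)
}

.addEvent <- function(env, ...) {
    env$counter <- env$counter + 1L
    f <- list(...)
    f$event_id <- sprintf("ev%06d", env$counter)
    env$events[[env$counter]] <- f
    f$event_id
}

.eventsToFrame <- function(evList) {
    if (!length(evList)) return(.emptyEvents())
    cols <- lapply(names(.EVENT_DEFAULTS), function(nm) {
        d <- .EVENT_DEFAULTS[[nm]]
        vapply(evList, function(e) {
            v <- e[[nm]]
            if (is.null(v)) d else {
                storage.mode(v) <- storage.mode(d); v
            }
        }, d)
    })
    names(cols) <- names(.EVENT_DEFAULTS)
    as.data.frame(cols, stringsAsFactors = FALSE)
}

## Sample a genomic position; segment classes are subtelomere-enriched.
.samplePos <- function(ctx, enrich, width = 1L) {
    pSub <- enrich * ctx$fSub / (enrich * ctx$fSub + (1 - ctx$fSub))
    if (stats::runif(1L) < pSub) {
        st <- ctx$stAll
        i <- sample.int(length(st), 1L, prob = width(st))
        lo <- start(st)[i]
        hi <- max(lo, end(st)[i] - width + 1L)
        list(chrom = as.character(seqnames(st))[i],
             pos = lo + sample.int(hi - lo + 1L, 1L) - 1L,
             subtelomeric = TRUE)
    } else {
        chrom <- sample(ctx$chromNames, 1L, prob = ctx$chromLens)
        pos <- sample.int(max(1L, ctx$chromLens[[chrom]] - width + 1L), 1L)
        list(chrom = chrom, pos = pos,
             subtelomeric = .posIsSubtel(ctx, chrom, pos))
    }
}

.posIsSubtel <- function(ctx, chrom, pos) {
    st <- ctx$stAll
    sel <- as.character(seqnames(st)) == chrom
    any(pos >= start(st)[sel] & pos <= end(st)[sel])
}

## Segment events are kept >= `pad` bp apart (not merely non-overlapping)
## so every event stays an individually resolvable region downstream.
.sampleSegment <- function(env, ctx, enrich, lenRange, what,
                           maxTries = 200L, pad = 1200L) {
    last <- NULL
    for (t in seq_len(maxTries)) {
        w <- if (lenRange[1L] == lenRange[2L]) lenRange[1L] else
            sample(lenRange[1L]:lenRange[2L], 1L)
        p <- .samplePos(ctx, enrich, width = w)
        last <- c(p, list(width = w))
        if (p$pos + w - 1L > ctx$chromLens[[p$chrom]]) next
        cand <- GRanges(p$chrom,
                        IRanges(max(1L, p$pos - pad),
                                min(ctx$chromLens[[p$chrom]],
                                    p$pos + w - 1L + pad)))
        if (!length(env$occupied) ||
            !length(suppressWarnings(
                GenomicRanges::findOverlaps(cand, env$occupied)))) {
            env$occupied <- suppressWarnings(c(env$occupied, cand))
            return(last)
        }
    }
    .stopf(paste0("could not place a non-overlapping %s segment after ",
                  "%d tries (last attempt %s:%d-%d)"),
           what, maxTries, last$chrom, last$pos, last$pos + last$width - 1L)
}

.simulateBranch <- function(env, blen, rates, state, ctx, enrich,
                            gainLR, lossLR, cnvLR, fsRej, allowEssential,
                            segPad = 1200L) {
    ids <- character()
    bases <- c("A", "C", "G", "T")
    orfs <- ctx$orfs

    ## ---- SNPs (stop-introducing proposals rejected)
    nSnp <- stats::rpois(1L, rates$snp * blen * ctx$G)
    for (k in seq_len(nSnp)) {
        repeat {
            p <- .samplePos(ctx, 1)
            if (p$pos %in% state$snpPos[[p$chrom]]) next
            refb <- ctx$refChars[[p$chrom]][p$pos]
            alt <- sample(setdiff(bases, refb), 1L)
            if (.introducesStop(p$chrom, p$pos, alt, orfs, ctx$refChars))
                next
            break
        }
        state$snpPos[[p$chrom]] <- c(state$snpPos[[p$chrom]], p$pos)
        ids <- c(ids, .addEvent(env, type = "snp", chrom = p$chrom,
                                start = p$pos, end = p$pos, ref = refb,
                                alt = alt, length = 0L,
                                subtelomeric = p$subtelomeric, lof = FALSE))
    }

    ## ---- short indels (1-10 bp), frameshift proposals mostly rejected
    nIndel <- stats::rpois(1L, rates$indel * blen * ctx$G)
    for (k in seq_len(nIndel)) {
        repeat {
            len <- sample(1:10, 1L)
            isIns <- stats::runif(1L) < 0.5
            p <- .samplePos(ctx, 1, width = if (isIns) 1L else len + 1L)
            hit <- .orfContaining(p$chrom, p$pos,
                                  p$pos + if (isIns) 0L else len, orfs)
            inOrf <- !is.na(hit)
            if (inOrf && len %% 3L != 0L && stats::runif(1L) < fsRej) next
            break
        }
        if (isIns) {
            altSeq <- paste(sample(bases, len, replace = TRUE),
                            collapse = "")
            refSeq <- ""
        } else {
            altSeq <- ""
            refSeq <- paste(
                ctx$refChars[[p$chrom]][(p$pos + 1L):(p$pos + len)],
                collapse = "")
        }
        lofFlag <- FALSE; kind <- NA_character_; orfId <- NA_character_
        relPos <- NA_real_
        if (inOrf && len %% 3L != 0L) {
            o <- orfs[hit]
            if (.indelInsideOrf(ctx, p$chrom, p$pos, refSeq, altSeq, o)) {
                lofFlag <- TRUE; kind <- "frameshift"
                orfId <- mcols(o)$orf_id
                relPos <- if (as.character(strand(o)) == "+")
                    (p$pos - start(o)) / width(o)
                else (end(o) - p$pos) / width(o)
            }
        }
        ids <- c(ids, .addEvent(
            env, type = if (isIns) "ins" else "del", chrom = p$chrom,
            start = p$pos, end = if (isIns) p$pos else p$pos + len,
            ref = refSeq, alt = altSeq, length = len,
            subtelomeric = p$subtelomeric, lof = lofFlag, lof_kind = kind,
            orf_id = orfId, rel_pos = relPos))
    }

    ## ---- segment gains / losses / tandem CNV (subtelomere-enriched)
    for (what in c("gain", "loss", "cnv")) {
        n <- stats::rpois(1L, rates[[what]] * blen * ctx$G)
        lenRange <- switch(what, gain = gainLR, loss = lossLR, cnv = cnvLR)
        for (k in seq_len(n)) {
            seg <- .sampleSegment(env, ctx, enrich, lenRange, what,
                                  pad = segPad)
            if (what == "gain") {
                ids <- c(ids, .addEvent(env, type = "gain",
                                        chrom = seg$chrom, start = seg$pos,
                                        end = seg$pos,
                                        alt = .randomDna(seg$width),
                                        length = seg$width,
                                        subtelomeric = seg$subtelomeric,
                                        lof = FALSE))
            } else if (what == "loss") {
                ids <- c(ids, .addEvent(env, type = "loss",
                                        chrom = seg$chrom, start = seg$pos,
                                        end = seg$pos + seg$width - 1L,
                                        length = seg$width,
                                        subtelomeric = seg$subtelomeric,
                                        lof = FALSE, copies = 0L))
            } else {
                ids <- c(ids, .addEvent(env, type = "cnv",
                                        chrom = seg$chrom, start = seg$pos,
                                        end = seg$pos + seg$width - 1L,
                                        length = seg$width,
                                        subtelomeric = seg$subtelomeric,
                                        lof = FALSE,
                                        copies = 1L + sample(1:3, 1L)))
            }
        }
    }

    ## ---- targeted loss-of-function events
    nLof <- stats::rpois(1L, rates$lof * blen * ctx$G)
    if (nLof > 0L) {
        eligible <- orfs[mcols(orfs)$class != "dubious" &
                         (allowEssential | !mcols(orfs)$essential)]
        eligible <- eligible[!(mcols(eligible)$orf_id %in% state$lofOrfs)]
        if (length(eligible) && length(env$occupied))
            eligible <- eligible[!suppressWarnings(
                IRanges::overlapsAny(eligible, env$occupied))]
        for (k in seq_len(min(nLof, length(eligible)))) {
            i <- sample.int(length(eligible), 1L)
            o <- eligible[i]
            eligible <- eligible[-i]
            ev <- .plantLof(env, o, ctx)
            if (!is.null(ev)) {
                env$occupied <- suppressWarnings(c(env$occupied, GRanges(
                    as.character(seqnames(o)),
                    IRanges(start(o), end(o)))))
                state$lofOrfs <- c(state$lofOrfs, mcols(o)$orf_id)
                ids <- c(ids, ev)
            }
        }
    }
    list(eventIds = ids, state = state)
}

.orfContaining <- function(chrom, s, e, orfs) {
    hits <- which(as.character(seqnames(orfs)) == chrom &
                  start(orfs) <= s & end(orfs) >= e)
    if (length(hits)) hits[1L] else NA_integer_
}

## Would substituting `alt` at (chrom, pos) create a stop codon in an ORF?
.introducesStop <- function(chrom, pos, alt, orfs, refChars) {
    hits <- which(as.character(seqnames(orfs)) == chrom &
                  start(orfs) <= pos & end(orfs) >= pos)
    for (h in hits) {
        o <- orfs[h]
        if (as.character(strand(o)) == "+") {
            off <- pos - start(o)
            c0 <- start(o) + 3L * (off %/% 3L)
            codon <- refChars[[chrom]][c0:(c0 + 2L)]
            codon[pos - c0 + 1L] <- alt
            codon <- paste(codon, collapse = "")
        } else {
            off <- end(o) - pos
            cEnd <- end(o) - 3L * (off %/% 3L)
            codon <- refChars[[chrom]][(cEnd - 2L):cEnd]
            codon[3L - (cEnd - pos)] <- alt
            codon <- .revcompChar(paste(codon, collapse = ""))
        }
        if (codon %in% .STOP_CODONS) return(TRUE)
    }
    FALSE
}

## Is the indel's equivalent region contained in the ORF interior?
.indelInsideOrf <- function(ctx, chrom, pos, refSeq, altSeq, orf) {
    chromSeq <- ctx$refChars[[chrom]]
    len <- max(nchar(refSeq), nchar(altSeq))
    a <- max(1L, pos - 40L)
    b <- min(length(chromSeq), pos + len + 40L)
    eq <- equivalentIndelRegion(paste(chromSeq[a:b], collapse = ""),
                                pos = pos - a + 1L, ref = refSeq,
                                alt = altSeq)
    lo <- a + eq[1L] - 1L
    hi <- a + eq[2L] - 1L
    lo >= start(orf) + 3L && hi <= end(orf) - 3L
}

## Plant a premature stop SNP (or NULL if no 1-substitution stop exists).
.plantLof <- function(env, orf, ctx) {
    chrom <- as.character(seqnames(orf))
    plus <- as.character(strand(orf)) == "+"
    nCodon <- width(orf) %/% 3L
    u <- stats::runif(1L, 0.05, 0.90)
    for (ci in max(2L, floor(u * nCodon)):(nCodon - 1L)) {
        if (plus) {
            c0 <- start(orf) + 3L * (ci - 1L)
            codon <- ctx$refChars[[chrom]][c0:(c0 + 2L)]
        } else {
            cEnd <- end(orf) - 3L * (ci - 1L)
            codon <- strsplit(.revcompChar(paste(
                ctx$refChars[[chrom]][(cEnd - 2L):cEnd], collapse = "")),
                "", fixed = TRUE)[[1L]]
        }
        for (pp in 1:3) {
            for (b in setdiff(c("A", "C", "G", "T"), codon[pp])) {
                mut <- codon; mut[pp] <- b
                if (!(paste(mut, collapse = "") %in% .STOP_CODONS)) next
                if (plus) {
                    gpos <- start(orf) + 3L * (ci - 1L) + (pp - 1L)
                    altb <- b
                } else {
                    gpos <- end(orf) - (3L * (ci - 1L) + (pp - 1L))
                    altb <- chartr("ACGT", "TGCA", b)
                }
                rel <- (3L * (ci - 1L)) / width(orf)
                return(.addEvent(
                    env, type = "snp", chrom = chrom, start = gpos,
                    end = gpos, ref = ctx$refChars[[chrom]][gpos],
                    alt = altb, length = 0L,
                    subtelomeric = .posIsSubtel(ctx, chrom, gpos),
                    lof = TRUE, lof_kind = "premature_stop",
                    orf_id = mcols(orf)$orf_id, rel_pos = rel))
            }
        }
    }
    NULL
}

## Apply a strain's events to the reference character vectors. Structural
## edits are spliced in one left-to-right pass (non-overlap is guaranteed
## at generation time); SNPs are direct substitutions beforehand.
.applyStrainEvents <- function(refChars, events, chromNames) {
    out <- lapply(chromNames, function(chrom) {
        chars <- refChars[[chrom]]
        ev <- events[events$chrom == chrom, , drop = FALSE]
        snps <- ev[ev$type == "snp", , drop = FALSE]
        if (nrow(snps)) chars[snps$start] <- snps$alt
        str <- ev[ev$type %in% c("ins", "del", "gain", "loss", "cnv"), ,
                  drop = FALSE]
        if (nrow(str)) {
            str <- str[order(str$start), , drop = FALSE]
            pieces <- list(); prev <- 1L
            for (r in seq_len(nrow(str))) {
                e <- str[r, ]
                if (e$type %in% c("ins", "gain")) {
                    pieces[[length(pieces) + 1L]] <- chars[prev:e$start]
                    pieces[[length(pieces) + 1L]] <-
                        strsplit(e$alt, "", fixed = TRUE)[[1L]]
                    prev <- e$start + 1L
                } else if (e$type %in% c("del", "loss")) {
                    s <- if (e$type == "del") e$start + 1L else e$start
                    if (s > prev)
                        pieces[[length(pieces) + 1L]] <- chars[prev:(s - 1L)]
                    prev <- e$end + 1L
                } else {  # cnv: tandem duplication
                    pieces[[length(pieces) + 1L]] <- chars[prev:e$end]
                    for (cc in seq_len(e$copies - 1L))
                        pieces[[length(pieces) + 1L]] <- chars[e$start:e$end]
                    prev <- e$end + 1L
                }
            }
            if (prev <= length(chars))
                pieces[[length(pieces) + 1L]] <- chars[prev:length(chars)]
            chars <- unlist(pieces, use.names = FALSE)
        }
        paste(chars, collapse = "")
    })
    names(out) <- chromNames
    DNAStringSet(unlist(out))
}

.copyNumberTruth <- function(events, carriers) {
    idx <- which(events$type %in% c("cnv", "loss"))
    rows <- lapply(idx, function(i) {
        who <- colnames(carriers)[carriers[i, ]]
        if (!length(who)) return(NULL)
        data.frame(strain = who, chrom = events$chrom[i],
                   start = events$start[i], end = events$end[i],
                   copies = events$copies[i], event_id = events$event_id[i])
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows)) do.call(rbind, rows) else
        data.frame(strain = character(), chrom = character(),
                   start = integer(), end = integer(), copies = integer(),
                   event_id = character())
}

.lofTruth <- function(events, carriers) {
    idx <- which(events$lof)
    rows <- lapply(idx, function(i) {
        who <- colnames(carriers)[carriers[i, ]]
        if (!length(who)) return(NULL)
        data.frame(strain = who, orf_id = events$orf_id[i],
                   event_id = events$event_id[i],
                   kind = events$lof_kind[i], rel_pos = events$rel_pos[i])
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows)) do.call(rbind, rows) else
        data.frame(strain = character(), orf_id = character(),
                   event_id = character(), kind = character(),
                   rel_pos = numeric())
}

#' Events carried by one strain
#' @param truth The \code{truth} element from \code{simulatePopulation}.
#' @param strain Strain (tip) label.
#' @return The subset of the event table carried by \code{strain}.
#' @export
strainEvents <- function(truth, strain) {
    truth$events[truth$carriers[, strain], , drop = FALSE]
}

#' Pairwise SNP distance matrix from simulation truth
#'
#' Number of SNP events carried by exactly one strain of each pair.
#' @param truth The \code{truth} element from \code{simulatePopulation}.
#' @return Symmetric integer matrix (strains x strains).
#' @export
snpDistanceMatrix <- function(truth) {
    snp <- truth$carriers[truth$events$type == "snp", , drop = FALSE]
    n <- ncol(snp)
    d <- matrix(0L, n, n, dimnames = list(colnames(snp), colnames(snp)))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
        d[i, j] <- d[j, i] <- sum(snp[, i] != snp[, j])
    d
}

#' Truth genome-content distance matrix
#'
#' Summed lengths of gain and loss events carried by exactly one strain of
#' each pair (material present in one and absent from the other).
#' @param truth The \code{truth} element from \code{simulatePopulation}.
#' @return Symmetric numeric matrix in bp.
#' @export
contentDistanceTruth <- function(truth) {
    sel <- truth$events$type %in% c("gain", "loss")
    len <- truth$events$length[sel]
    car <- truth$carriers[sel, , drop = FALSE]
    n <- ncol(car)
    d <- matrix(0, n, n, dimnames = list(colnames(car), colnames(car)))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
        d[i, j] <- d[j, i] <- sum(len[car[, i] != car[, j]])
    d
}
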