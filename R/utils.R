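## Internal helpers shared across modules.

## Evaluate expr with a private RNG stream; global .Random.seed restored.
.withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(seed)
    }
    force(expr)
}

.randomDnaVector <- function(n) {
    sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

.randomDna <- function(n) paste(.randomDnaVector(n), collapse = "")

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.CODONS <- {
    b <- c("A", "C", "G", "T")
    all <- as.vector(outer(outer(b, b, paste0), b, paste0))
    all
}
.SENSE_CODONS <- setdiff(.CODONS, .STOP_CODONS)

.revcompChar <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Maximal runs of TRUE in a logical vector -> matrix of (start, end), 1-based.
.trueRuns <- function(flag) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    cbind(start = starts[keep], end = ends[keep])
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
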