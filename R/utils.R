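# Internal helpers shared across modules.

# Derive a child seed from the master seed by a fixed offset, kept inside
# the 32-bit integer range so set.seed() accepts it.
childSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) * 7919 + offset) %% 2147483629)
}

# Run code under a child seed without disturbing the caller's RNG state.
withChildSeed <- function(seed, offset, code) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(childSeed(seed, offset))
    force(code)
}

# deterministic number formatting for all text outputs (no scientific
# notation drift between runs/platforms)
fmtNum <- function(x, digits = 6) {
    ifelse(is.na(x), "NA",
           formatC(x, format = "fg", digits = digits, flag = "#"))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# write a data.frame as a plain TSV, deterministically
writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

readTsv <- function(path, ...) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE, ...)
}

# 1-based midpoint of GRanges intervals
grMid <- function(gr) {
    as.integer(floor((GenomicRanges::start(gr) +
                      GenomicRanges::end(gr)) / 2))
}
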