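# Shared fixture builders: everything is constructed in code, no files.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(S4Vectors)
    library(GenomeInfoDb)
})

tinySeqinfo <- function(lens = c(chr1 = 1000000L, chr2 = 800000L)) {
    Seqinfo(seqnames = names(lens), seqlengths = unname(lens))
}

# peak GRanges in the package's internal convention (1-based closed)
makePeaks <- function(chrom, start, end, summit = NULL, rpmIP = 10,
                      rpmInput = 1, pvalue = 1e-6, mark = "H3K27ac",
                      si = tinySeqinfo()) {
    gr <- GRanges(chrom, IRanges(start, end))
    n <- length(gr)
    if (is.null(summit)) summit <- floor((start + end) / 2)
    gr$name <- sprintf("pk%03d", seq_len(n))
    gr$summit <- as.integer(summit)
    gr$rpmIP <- rep_len(rpmIP, n)
    gr$rpmInput <- rep_len(rpmInput, n)
    gr$pvalue <- rep_len(pvalue, n)
    gr$mark <- rep_len(mark, n)
    seqlevels(gr) <- seqlevels(si)
    seqinfo(gr) <- si
    gr
}

makeTss <- function(chrom, pos, strand = "+", gene_id = NULL,
                    si = tinySeqinfo()) {
    gr <- GRanges(chrom, IRanges(pos, width = 1L), strand = strand)
    gr$gene_id <- if (is.null(gene_id))
        sprintf("g%03d", seq_along(gr)) else gene_id
    seqinfo(gr) <- si
    gr
}

# coverage track from a per-base read-density vector on one chromosome
# (interval per base, so partial-overlap pro-rating is exact)
trackFromVector <- function(dens, chrom = "chr1", total = 1e6,
                            si = NULL) {
    if (is.null(si))
        si <- Seqinfo(seqnames = chrom, seqlengths = length(dens))
    gr <- GRanges(chrom, IRanges(seq_along(dens), width = 1L))
    gr$score <- dens
    seqinfo(gr) <- si
    CoverageTrack(cov = gr, totalReads = total, binSize = 1L)
}

# build a ChainSet directly from block structure (uses the same internal
# record builder as the parser, validated by the class)
makeChainSet <- function(..., sourceLens, targetLens) {
    recs <- lapply(list(...), function(a)
        do.call(CREconserve:::chainRecord, a))
    ChainSet(chains = recs,
             sourceSeqinfo = Seqinfo(names(sourceLens),
                                     unname(sourceLens)),
             targetSeqinfo = Seqinfo(names(targetLens),
                                     unname(targetLens)))
}

# independent per-base mapping oracle: maps every base of the 0-based
# half-open interval [s0, e0) through every chain block, then applies the
# minimum-match rule. Mirrors the liftOver contract, not the implementation.
oracleMapInterval <- function(chainSet, chrom, s0, e0, minMatch = 0.2,
                              allowMultiple = FALSE) {
    bases <- s0:(e0 - 1L)
    perChain <- list()
    for (ch in chains(chainSet)) {
        if (ch$sName != chrom) next
        tgt <- integer(0)
        for (b in bases) {
            k <- which(b >= ch$blockSrcStart & b < ch$blockSrcEnd)
            for (kk in k) {
                t <- ch$blockTgtStart[kk] + (b - ch$blockSrcStart[kk])
                if (ch$tStrand == "-") t <- ch$tSize - 1L - t
                tgt <- c(tgt, t)
            }
        }
        if (length(tgt))
            perChain[[length(perChain) + 1L]] <-
                list(ch = ch, nBases = length(tgt), tgt = tgt)
    }
    if (!length(perChain)) return(list(mapped = FALSE, reason = "no_chain"))
    if (length(perChain) > 1L && !allowMultiple)
        return(list(mapped = FALSE, reason = "split_across_chains"))
    best <- perChain[[which.max(vapply(perChain, `[[`, numeric(1),
                                       "nBases"))]]
    frac <- best$nBases / (e0 - s0)
    if (frac < minMatch)
        return(list(mapped = FALSE, reason = "below_min_match",
                    matchFrac = frac))
    list(mapped = TRUE, tName = best$ch$tName,
         tStart = min(best$tgt) + 1L, tEnd = max(best$tgt) + 1L,
         tStrand = best$ch$tStrand, matchFrac = frac)
}

# independent elbow oracle: plain-loop scan of the scaled rank curve
oracleElbow <- function(signals) {
    s <- sort(signals)
    n <- length(s)
    best <- -Inf; idx <- NA_integer_
    for (i in seq_len(n)) {
        x <- (i - 1) / (n - 1)
        y <- (s[i] - s[1]) / (s[n] - s[1])
        if (x - y >= best) { best <- x - y; idx <- i }  # ties -> highest
    }
    list(index = idx, cutoff = s[idx])
}

# exact Wilcoxon rank-sum p by full enumeration of rank assignments,
# mirroring R's two-sided doubling rule
oracleWilcox <- function(a, b, alternative = "two.sided") {
    n <- length(a); m <- length(b)
    r <- rank(c(a, b))
    W <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    idx <- utils::combn(n + m, n)
    Wall <- apply(idx, 2L, function(ii) sum(r[ii]) - n * (n + 1) / 2)
    switch(alternative,
           less = mean(Wall <= W),
           greater = mean(Wall >= W),
           two.sided = {
               p <- if (W > n * m / 2) mean(Wall >= W) else mean(Wall <= W)
               min(2 * p, 1)
           })
}

# brute-force maximal cliques of the mutual graph by 2^n subset scan
oracleCliques <- function(adj) {
    n <- nrow(adj)
    mutual <- adj & t(adj)
    diag(mutual) <- TRUE
    nodes <- rownames(adj)
    isClique <- function(ii) all(mutual[ii, ii])
    subsets <- lapply(seq_len(2^n - 1L), function(mask)
        which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L))
    cl <- Filter(isClique, subsets)
    maximal <- Filter(function(ii)
        !any(vapply(cl, function(jj)
            length(jj) > length(ii) && all(ii %in% jj), logical(1))), cl)
    out <- lapply(maximal, function(ii) sort(nodes[ii]))
    out[order(-lengths(out),
              vapply(out, paste, character(1), collapse = ","))]
}

# per-base RPM oracle over a dense expansion of the track
oracleRpm <- function(track, chrom, s, e) {
    gr <- coverageRanges(track)
    gr <- gr[as.character(seqnames(gr)) == chrom]
    dens <- numeric(max(end(gr)))
    for (i in seq_along(gr)) {
        ii <- start(gr)[i]:end(gr)[i]
        dens[ii] <- dens[ii] + gr$score[i] / width(gr)[i]
    }
    1e6 * sum(dens[s:min(e, length(dens))]) / totalReads(track)
}
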