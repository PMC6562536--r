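#' Bin a coverage track into fixed-width genome bins
#'
#' Tiles every chromosome with \code{binSize} bins (default 10 kb, the
#' resolution used for replicate-concordance checks) and assigns each
#' coverage interval's reads to bins proportionally to overlap.
#'
#' @param track a \code{\link{CoverageTrack}}.
#' @param binSize bin width in bp.
#' @return GRanges tiling the genome with a \code{score} column (reads).
#' @export
binCoverage <- function(track, binSize = 10000L) {
    gr <- coverageRanges(track)
    si <- seqinfo(gr)
    if (any(is.na(seqlengths(si))))
        stopf("coverage track needs seqlengths to be binned")
    bins <- GenomicRanges::tileGenome(si, tilewidth = binSize,
                                      cut.last.tile.in.chrom = TRUE)
    hits <- findOverlaps(bins, gr)
    ov <- pintersect(bins[queryHits(hits)], gr[subjectHits(hits)])
    frac <- width(ov) / width(gr[subjectHits(hits)])
    reads <- gr$score[subjectHits(hits)] * frac
    score <- rep(0, length(bins))
    agg <- tapply(reads, queryHits(hits), sum)
    score[as.integer(names(agg))] <- as.numeric(agg)
    bins$score <- score
    bins
}

#' Pearson correlation between two replicate binned tracks
#'
#' Computes the Pearson correlation of per-bin read counts between two
#' biological replicates on an identical binning grid; bins that are zero
#' in both replicates are retained, as in standard replicate-concordance QC.
#'
#' @param binsA,binsB GRanges from \code{\link{binCoverage}} on the same
#'   grid, or plain numeric vectors of equal length.
#' @return Pearson r.
#' @export
replicateCorrelation <- function(binsA, binsB) {
    if (is(binsA, "GRanges")) {
        if (length(binsA) != length(binsB) ||
            !identical(as.character(seqnames(binsA)),
                       as.character(seqnames(binsB))) ||
            !identical(start(binsA), start(binsB)) ||
            !identical(end(binsA), end(binsB)))
            stopf("replicate tracks are binned on different grids")
        a <- binsA$score; b <- binsB$score
    } else {
        if (length(binsA) != length(binsB))
            stopf("replicate bin vectors differ in length")
        a <- binsA; b <- binsB
    }
    stats::cor(a, b, method = "pearson")
}

#' Remove peaks failing the Poisson p-value cut
#'
#' Narrow peaks with p > 0.01 and broad peaks with p > 0.1 are removed;
#' peaks exactly at the boundary are kept (the removal rule is strictly
#' "greater than").
#'
#' @param peaks GRanges with a \code{pvalue} column.
#' @param mode "narrow" or "broad".
#' @return the surviving peaks, order preserved.
#' @export
filterPeaksByPvalue <- function(peaks, mode = c("narrow", "broad")) {
    mode <- match.arg(mode)
    cut <- if (mode == "narrow") 0.01 else 0.1
    peaks[!is.na(peaks$pvalue) & peaks$pvalue <= cut]
}

#' Reads-per-million over regions of a coverage track
#'
#' RPM = 1e6 * (reads overlapping the region) / (declared library size).
#' Reads of an interval partially overlapping the region are pro-rated by
#' the overlap fraction, assuming uniform read density within the interval
#' (the resolution at which bedGraph tracks are emitted).
#'
#' @param track a \code{\link{CoverageTrack}}.
#' @param regions GRanges.
#' @return numeric RPM vector, one value per region.
#' @export
rpmInRegion <- function(track, regions) {
    gr <- coverageRanges(track)
    sl <- seqlengths(seqinfo(gr))
    rs <- as.character(seqnames(regions))
    known <- rs %in% GenomeInfoDb::seqnames(seqinfo(gr))
    if (any(known & !is.na(sl[rs]) & end(regions) > sl[rs], na.rm = TRUE) ||
        any(start(regions) < 1L))
        stopf("region outside track bounds")
    hits <- findOverlaps(regions, gr)
    reads <- rep(0, length(regions))
    if (length(hits)) {
        ov <- pintersect(regions[queryHits(hits)], gr[subjectHits(hits)])
        frac <- width(ov) / width(gr[subjectHits(hits)])
        contrib <- gr$score[subjectHits(hits)] * frac
        agg <- tapply(contrib, queryHits(hits), sum)
        reads[as.integer(names(agg))] <- as.numeric(agg)
    }
    1e6 * reads / totalReads(track)
}

#' Two-fold RPM enrichment filter
#'
#' Keeps a peak iff RPM_IP >= 2 * RPM_Input and RPM_IP - RPM_Input > 1.
#' When IP and input tracks are supplied, RPM values are (re)computed over
#' the peak intervals and stored back on the returned peaks; otherwise the
#' existing \code{rpmIP}/\code{rpmInput} columns are used.
#'
#' @param peaks GRanges with rpmIP/rpmInput columns (or tracks supplied).
#' @param ipTrack,inputTrack optional \code{\link{CoverageTrack}}s.
#' @return the surviving peaks, order preserved, rpm columns populated.
#' @export
enrichmentFilter <- function(peaks, ipTrack = NULL, inputTrack = NULL) {
    if (!is.null(ipTrack)) peaks$rpmIP <- rpmInRegion(ipTrack, peaks)
    if (!is.null(inputTrack))
        peaks$rpmInput <- rpmInRegion(inputTrack, peaks)
    if (is.null(peaks$rpmIP) || is.null(peaks$rpmInput) ||
        anyNA(peaks$rpmIP) || anyNA(peaks$rpmInput))
        stopf("enrichmentFilter needs rpmIP and rpmInput (supply tracks)")
    keep <- peaks$rpmIP >= 2 * peaks$rpmInput &
        (peaks$rpmIP - peaks$rpmInput) > 1
    peaks[keep]
}

#' Standardize elements to a fixed width centred on the summit
#'
#' Every element becomes a \code{width}-bp window centred on its summit
#' (2 kb by default, the unified element size used before cross-species
#' mapping). Windows running off a chromosome end are clipped, not dropped
#' — dropping would bias telomeric elements — and flagged in the
#' \code{clipped} column.
#'
#' @param elements GRanges with a \code{summit} column (1-based position).
#' @param chromSizes Seqinfo (defaults to the elements' own seqinfo).
#' @param width standardized width in bp.
#' @return GRanges of standardized windows; metadata columns are carried
#'   over, with a logical \code{clipped} column added.
#' @export
standardizeElements <- function(elements, chromSizes = NULL, width = 2000L) {
    if (is.null(elements$summit)) stopf("elements need a 'summit' column")
    if (is.null(chromSizes)) chromSizes <- seqinfo(elements)
    sl <- seqlengths(chromSizes)[as.character(seqnames(elements))]
    if (anyNA(sl)) stopf("chromosome lengths unknown for some elements")
    if (any(elements$summit < 1L | elements$summit > sl))
        stopf("summit outside chromosome bounds")
    half <- as.integer(width / 2)
    s <- elements$summit - half
    e <- elements$summit + half - 1L
    clipped <- s < 1L | e > sl
    s <- pmax(s, 1L)
    e <- pmin(e, sl)
    out <- GRanges(seqnames(elements), IRanges(s, e))
    mcols(out) <- mcols(elements)
    out$clipped <- clipped
    seqinfo(out) <- merge(seqinfo(elements), chromSizes)
    out
}
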