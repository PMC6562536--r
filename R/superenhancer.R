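#' Stitch enhancers into candidate super-enhancer regions
#'
#' Two enhancers on the same chromosome are joined when the gap between them
#' (bases strictly between the end of one and the start of the next) is at
#' most \code{stitchBp} (ROSE default 12,500); joining is transitive, and a
#' stitched region spans from the first constituent's start to the last
#' constituent's end. With \code{tssExclude = TRUE}, enhancers overlapping a
#' TSS window are removed before stitching (off by default: the enhancer
#' definition has already excluded TSS-proximal peaks).
#'
#' @param enhancers GRanges of enhancers (rpmIP/rpmInput columns are used
#'   downstream for scoring).
#' @param config a \code{\link{RoseConfig}}.
#' @param tss,annoConfig TSS records and window config, only needed when
#'   \code{tssExclude} is TRUE.
#' @return GRanges of stitched regions; \code{constituents} is an
#'   IntegerList of indices into the (possibly TSS-filtered) enhancer input,
#'   returned as the \code{enhancers} metadata attribute.
#' @export
stitchEnhancers <- function(enhancers, config = RoseConfig(),
                            tss = NULL, annoConfig = AnnotationConfig()) {
    if (config@tssExclude) {
        if (is.null(tss)) stopf("tssExclude = TRUE requires TSS records")
        win <- tssWindows(tss, annoConfig)
        enhancers <- enhancers[countOverlaps(enhancers, win,
                                             ignore.strand = TRUE) == 0L]
    }
    if (!length(enhancers)) {
        out <- GRanges()
        out$constituents <- IRanges::IntegerList()
        metadata(out)$enhancers <- enhancers
        return(out)
    }
    # reduce() merges ranges separated by < min.gapwidth bases, so a gap of
    # exactly stitchBp still joins
    red <- reduce(enhancers, min.gapwidth = config@stitchBp + 1L,
                  ignore.strand = TRUE, with.revmap = TRUE)
    out <- GRanges(seqnames(red), IRanges(start(red), end(red)))
    out$constituents <- red$revmap
    out$name <- sprintf("stitched_%05d", seq_along(out))
    seqinfo(out) <- seqinfo(enhancers)
    metadata(out)$enhancers <- enhancers
    out
}

#' Score stitched regions by input-subtracted signal
#'
#' Region signal is the sum over constituent enhancer intervals (stitched
#' gaps excluded, as in ROSE) of RPM_IP - RPM_Input. When coverage tracks
#' are supplied the RPM values are computed over the constituent intervals;
#' otherwise the constituents' stored rpmIP/rpmInput are used. A region
#' whose input exceeds IP gets a negative signal and is flagged.
#'
#' @param regions stitched regions from \code{\link{stitchEnhancers}}.
#' @param ipTrack,inputTrack optional \code{\link{CoverageTrack}}s.
#' @return regions with \code{signal} and \code{negativeSignal} columns.
#' @export
scoreStitchedRegions <- function(regions, ipTrack = NULL, inputTrack = NULL) {
    enh <- metadata(regions)$enhancers
    if (is.null(enh)) stopf("regions lack constituent enhancer metadata")
    ip <- if (!is.null(ipTrack)) rpmInRegion(ipTrack, enh) else enh$rpmIP
    inp <- if (!is.null(inputTrack)) rpmInRegion(inputTrack, enh)
           else enh$rpmInput
    if (is.null(ip) || is.null(inp))
        stopf("constituents lack rpm columns and no tracks were supplied")
    per <- ip - inp
    regions$signal <- vapply(regions$constituents,
                             function(ii) sum(per[ii]), numeric(1))
    regions$negativeSignal <- regions$signal < 0
    regions
}

#' Geometric elbow cutoff on a ranked signal curve
#'
#' Signals are sorted ascending, ranks scaled to x in [0,1] and signals
#' min-max scaled to y in [0,1]; the cutoff index maximizes x - y, i.e. the
#' tangent point where the scaled curve's slope reaches 1 (the ROSE
#' hockey-stick criterion). Ties break to the highest index (fewest
#' super-enhancers). Regions with signal strictly above the cutoff value
#' are super-enhancers.
#'
#' @param signals numeric vector (any order; at least 3 values).
#' @return list with \code{cutoff} (signal value), \code{index} (1-based
#'   index into the ascending-sorted signals) and \code{isSuper} (logical,
#'   aligned with the input order).
#' @export
elbowCutoff <- function(signals) {
    if (length(signals) < 3L) stopf("need at least 3 signals for a cutoff")
    if (diff(range(signals)) == 0) {
        warnf("all signals equal: no elbow, zero super-enhancers")
        return(list(cutoff = NA_real_, index = NA_integer_,
                    isSuper = rep(FALSE, length(signals))))
    }
    s <- sort(signals)
    n <- length(s)
    x <- (seq_len(n) - 1) / (n - 1)
    y <- (s - s[1L]) / (s[n] - s[1L])
    d <- x - y
    idx <- max(which(d == max(d)))  # tie-break to highest index
    cutoff <- s[idx]
    list(cutoff = cutoff, index = idx, isSuper = signals > cutoff)
}

#' Call super-enhancers from an enhancer set
#'
#' Convenience wrapper: stitch, score, apply the elbow cutoff, and rank.
#'
#' @inheritParams stitchEnhancers
#' @inheritParams scoreStitchedRegions
#' @return stitched regions with \code{signal}, \code{rank} (1 = strongest)
#'   and \code{isSuper} columns, sorted by signal descending.
#' @export
callSuperEnhancers <- function(enhancers, config = RoseConfig(),
                               ipTrack = NULL, inputTrack = NULL,
                               tss = NULL, annoConfig = AnnotationConfig()) {
    st <- stitchEnhancers(enhancers, config, tss, annoConfig)
    st <- scoreStitchedRegions(st, ipTrack, inputTrack)
    cut <- elbowCutoff(st$signal)
    st$isSuper <- cut$isSuper
    ord <- order(-st$signal, as.character(seqnames(st)), start(st))
    st <- st[ord]
    st$rank <- seq_along(st)
    metadata(st)$cutoff <- cut$cutoff
    st
}

#' Assign genes to stitched regions
#'
#' Default mode \code{overlap_then_nearest}: all genes whose TSS lies inside
#' the stitched interval; when none does, the single nearest TSS by bp
#' distance. Mode \code{nearest_tss}: the single nearest TSS only. Distance
#' ties break to the lexicographically first gene_id.
#'
#' @param regions GRanges of stitched regions.
#' @param tss GRanges of TSS positions with gene_id.
#' @param mode assignment rule (defaults to the region's RoseConfig default).
#' @return character list (one element per region) of assigned gene ids.
#' @export
assignGenes <- function(regions, tss,
                        mode = c("overlap_then_nearest", "nearest_tss")) {
    mode <- match.arg(mode)
    if (length(tss) == 0L) stopf("empty TSS set")
    res <- vector("list", length(regions))
    hits <- findOverlaps(regions, tss, ignore.strand = TRUE)
    for (i in seq_along(regions)) {
        inside <- sort(tss$gene_id[subjectHits(hits)[queryHits(hits) == i]])
        if (mode == "overlap_then_nearest" && length(inside)) {
            res[[i]] <- inside
        } else {
            d <- distance(regions[i], tss, ignore.strand = TRUE)
            d[is.na(d)] <- Inf  # other chromosomes never win
            cand <- tss$gene_id[d == min(d)]
            res[[i]] <- sort(cand)[1L]
        }
    }
    res
}
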