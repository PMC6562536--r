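#' Strand-aware TSS windows
#'
#' The promoter-proximal window spans \code{upstreamBp} upstream through
#' \code{downstreamBp} downstream of each TSS (defaults 2.5 kb / 1.5 kb,
#' the window used both to exclude promoter-proximal H3K27ac peaks from the
#' enhancer set and to anchor broad H3K4me3 domains). Windows are clipped
#' at chromosome bounds when lengths are known.
#'
#' @param tss GRanges of width-1 TSS positions with strand.
#' @param config an \code{\link{AnnotationConfig}}.
#' @return GRanges of TSS windows, one per TSS, gene_id carried over.
#' @export
tssWindows <- function(tss, config = AnnotationConfig()) {
    st <- as.character(strand(tss))
    if (any(st == "*")) stopf("TSS records must be stranded")
    pos <- start(tss)
    up <- config@upstreamBp; down <- config@downstreamBp
    s <- ifelse(st == "+", pos - up, pos - down)
    e <- ifelse(st == "+", pos + down - 1L, pos + up - 1L)
    sl <- seqlengths(seqinfo(tss))[as.character(seqnames(tss))]
    s <- pmax(s, 1L)
    e <- ifelse(is.na(sl), e, pmin(e, sl))
    out <- GRanges(seqnames(tss), IRanges(s, e), strand = st)
    out$gene_id <- tss$gene_id
    seqinfo(out) <- seqinfo(tss)
    out
}

#' Classify peaks into promoters, active promoters and enhancers
#'
#' Every H3K4me3 peak is a promoter; promoters overlapping (>= 1 bp) any
#' H3K27ac peak are active promoters and the rest are poised promoters.
#' H3K27ac peaks with zero overlap with any H3K4me3 peak and zero overlap
#' with any TSS window are enhancers. H3K27ac peaks that fail the enhancer
#' criteria and are not paired with a promoter are retained with class
#' \code{unclassified_h3k27ac} rather than silently dropped.
#'
#' @param h3k4me3,h3k27ac QC-passed peak GRanges (see \code{readPeaks}).
#' @param tss GRanges of TSS positions (must be non-empty: the enhancer
#'   definition is undefined without TSS).
#' @param config an \code{\link{AnnotationConfig}}.
#' @return GRanges of elements with an \code{elementClass} column in
#'   \{active_promoter, poised_promoter, enhancer, unclassified_h3k27ac\}
#'   (active + poised promoters together are the promoter set).
#' @export
classifyElements <- function(h3k4me3, h3k27ac, tss,
                             config = AnnotationConfig()) {
    if (length(tss) == 0L)
        stopf("empty TSS set: the enhancer definition requires TSS windows")
    windows <- tssWindows(tss, config)
    active <- countOverlaps(h3k4me3, h3k27ac, ignore.strand = TRUE) > 0L
    prom <- h3k4me3
    prom$elementClass <- ifelse(active, "active_promoter", "poised_promoter")

    inK4 <- countOverlaps(h3k27ac, h3k4me3, ignore.strand = TRUE) > 0L
    inWin <- countOverlaps(h3k27ac, windows, ignore.strand = TRUE) > 0L
    enh <- h3k27ac[!inK4 & !inWin]
    if (length(enh)) enh$elementClass <- "enhancer"
    uncl <- h3k27ac[!inK4 & inWin]
    if (length(uncl)) uncl$elementClass <- "unclassified_h3k27ac"

    out <- c(prom, enh, uncl)
    out$name <- sprintf("%s_%05d", out$elementClass, seq_along(out))
    out
}

#' Call broad H3K4me3 domains
#'
#' A broad domain is an H3K4me3 peak that overlaps at least one TSS window
#' and whose original width exceeds \code{broadMinWidthBp} (strictly greater
#' than 4 kb by default). Width is measured on the original peak — the 2 kb
#' standardized form would make the rule unsatisfiable.
#'
#' @inheritParams classifyElements
#' @return GRanges of broad domains with elementClass "broad_domain".
#' @export
callBroadDomains <- function(h3k4me3, tss, config = AnnotationConfig()) {
    windows <- tssWindows(tss, config)
    keep <- countOverlaps(h3k4me3, windows, ignore.strand = TRUE) > 0L &
        width(h3k4me3) > config@broadMinWidthBp
    out <- h3k4me3[keep]
    if (length(out)) {
        out$elementClass <- "broad_domain"
        out$name <- sprintf("broad_domain_%05d", seq_along(out))
    }
    out
}

#' Top-ranked enhancers by H3K27ac intensity
#'
#' Sorts enhancers by IP RPM descending (ties broken by genome order:
#' chromosome, then start) and returns the first \code{n} — the ranking
#' used for enrichment analyses over the strongest 3000 enhancers.
#'
#' @param enhancers GRanges with an \code{rpmIP} column.
#' @param n how many to keep (all, if fewer are available).
#' @return ordered GRanges.
#' @export
rankTopEnhancers <- function(enhancers, n = 3000L) {
    if (is.null(enhancers$rpmIP)) stopf("enhancers need an 'rpmIP' column")
    ord <- order(-enhancers$rpmIP,
                 as.character(seqnames(enhancers)),
                 start(enhancers))
    enhancers[ord][seq_len(min(n, length(enhancers)))]
}

#' Per-class element counts
#' @param ... GRanges of elements with elementClass columns.
#' @return data.frame with class and count columns.
#' @export
elementCounts <- function(...) {
    cls <- unlist(lapply(list(...), function(gr)
        if (length(gr)) gr$elementClass else character()))
    tab <- table(cls)
    data.frame(class = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
}
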