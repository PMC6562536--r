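#' Quantile-normalize an expression matrix
#'
#' Forces every column (sample/species) onto the identical distribution:
#' after normalization each column's sorted values equal the per-rank
#' across-column mean; ties within a column receive the mean of the tied
#' ranks' reference values. Delegates to limma's quantile normalization,
#' whose tie handling matches this definition.
#'
#' @param mat numeric matrix, genes x samples, at least 2 columns.
#' @return normalized matrix, dimnames preserved.
#' @export
quantileNormalize <- function(mat) {
    if (!is.matrix(mat) || !length(mat)) stopf("need a non-empty matrix")
    if (ncol(mat) < 2L) stopf("quantile normalization needs >= 2 columns")
    out <- limma::normalizeQuantiles(mat, ties = TRUE)
    dimnames(out) <- dimnames(mat)
    out
}

#' Apply differential-expression thresholds
#'
#' A gene is differentially expressed iff |log2 fold change| >= lfc (the
#' fold cut is inclusive), p-value < p and FDR < fdr (both strict).
#' Direction is up_in_A for positive fold changes, down_in_A for negative,
#' ns otherwise. When the table has no FDR column and \code{computeFdr} is
#' TRUE, Benjamini-Hochberg FDR is computed from the p-values.
#'
#' @param de data.frame with gene_id, log2_fold, pvalue and optionally fdr.
#' @param lfc,p,fdr thresholds (defaults 2, 0.001, 0.01).
#' @param computeFdr compute BH FDR from p-values when fdr is absent.
#' @return list: \code{records} (the table with fdr and direction columns)
#'   and \code{counts} (up_in_A, down_in_A, ns).
#' @export
applyDeThresholds <- function(de, lfc = 2, p = 0.001, fdr = 0.01,
                              computeFdr = FALSE) {
    if (is.null(de$fdr)) {
        if (!computeFdr)
            stopf("no 'fdr' column and computeFdr = FALSE")
        de$fdr <- stats::p.adjust(de$pvalue, method = "BH")
    }
    sig <- abs(de$log2_fold) >= lfc & de$pvalue < p & de$fdr < fdr
    de$direction <- ifelse(!sig, "ns",
                           ifelse(de$log2_fold > 0, "up_in_A", "down_in_A"))
    counts <- c(up_in_A = sum(de$direction == "up_in_A"),
                down_in_A = sum(de$direction == "down_in_A"),
                ns = sum(de$direction == "ns"))
    list(records = de, counts = counts)
}

#' Histone intensity in TSS-flanking windows
#'
#' RPM of a coverage track over the +/- \code{flankBp} window around each
#' TSS (1 kb by default), clipped at chromosome bounds.
#'
#' @param tss GRanges of TSS positions.
#' @param track a \code{\link{CoverageTrack}}.
#' @param flankBp flank size in bp.
#' @return numeric RPM per gene, named by gene_id when available.
#' @export
tssFlankIntensity <- function(tss, track, flankBp = 1000L) {
    sl <- seqlengths(seqinfo(coverageRanges(track)))
    s <- pmax(start(tss) - flankBp, 1L)
    lens <- sl[as.character(seqnames(tss))]
    e <- start(tss) + flankBp - 1L
    e <- ifelse(is.na(lens), e, pmin(e, lens))
    win <- GRanges(seqnames(tss), IRanges(s, e))
    rpm <- rpmInRegion(track, win)
    if (!is.null(tss$gene_id)) names(rpm) <- tss$gene_id
    rpm
}

#' Link elements to their nearest gene
#'
#' Nearest-TSS assignment by bp distance from the element interval (0 for a
#' TSS inside the element), with distance ties broken by lexicographic
#' gene_id — the same rule as \code{\link{assignGenes}} in nearest mode.
#'
#' @param elements GRanges.
#' @param tss GRanges of TSS positions with gene_id.
#' @return character vector of gene ids, one per element.
#' @export
linkElementsToGenes <- function(elements, tss) {
    if (length(tss) == 0L) stopf("empty TSS set")
    chrom <- as.character(seqnames(elements))
    tchrom <- as.character(seqnames(tss))
    out <- rep(NA_character_, length(elements))
    for (cc in unique(chrom)) {
        ei <- which(chrom == cc)
        ti <- which(tchrom == cc)
        if (!length(ti))
            stopf("no TSS on chromosome '%s'", cc)
        pos <- start(tss)[ti]
        ids <- tss$gene_id[ti]
        s <- start(elements)[ei]; e <- end(elements)[ei]
        # interval-to-point distance, dense per chromosome; gap convention
        # (adjacent = 0) matching GenomicRanges::distance
        d <- pmax(outer(s, pos, `-`) - 1,
                  outer(e, pos, function(ee, pp) pp - ee) - 1)
        d[d < 0] <- 0
        for (r in seq_along(ei)) {
            cand <- ids[d[r, ] == min(d[r, ])]
            out[ei[r]] <- sort(cand)[1L]
        }
    }
    out
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided by default; the exact null distribution is enumerated when the
#' smaller group has at most 8 observations and there are no ties, and the
#' normal approximation with tie correction is used otherwise.
#'
#' @param a,b numeric samples (both non-empty).
#' @param alternative "two.sided" (default), "less" or "greater" (of a
#'   relative to b).
#' @return list with \code{statistic} (W), \code{p.value} and
#'   \code{method} ("exact" or "normal_approx").
#' @export
compareGroups <- function(a, b,
                          alternative = c("two.sided", "less", "greater")) {
    alternative <- match.arg(alternative)
    if (!length(a) || !length(b)) stopf("both groups must be non-empty")
    ties <- anyDuplicated(c(a, b)) > 0L
    exact <- min(length(a), length(b)) <= 8L && !ties
    ht <- suppressWarnings(
        stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                           correct = !exact))
    list(statistic = unname(ht$statistic), p.value = ht$p.value,
         method = if (exact) "exact" else "normal_approx")
}
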