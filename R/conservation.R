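#' Map intervals to a target genome through alignment chains
#'
#' liftOver-style minimum-match mapping. For each interval, the aligned
#' bases falling inside the blocks of each chain are counted; an interval
#' maps iff its aligned bases lie on a single chain (unless
#' \code{allowMultiple}) and the mapped fraction (aligned bases / interval
#' width) is at least \code{minMatch}. The target interval is the span of
#' the mapped bases; blocks of a '-'-strand chain yield coordinates
#' reflected about the target chromosome, reported on forward coordinates
#' with strand '-'.
#'
#' @param intervals GRanges in source coordinates.
#' @param chainSet a \code{\link{ChainSet}}.
#' @param config a \code{\link{LiftOverConfig}}.
#' @return data.frame with one row per interval: \code{mapped} (logical),
#'   \code{reason} for failures ("no_chain", "split_across_chains",
#'   "below_min_match"), target \code{tName}, \code{tStart}, \code{tEnd}
#'   (1-based closed), \code{tStrand}, \code{matchedBases} and
#'   \code{matchFrac}.
#' @export
mapIntervals <- function(intervals, chainSet, config = LiftOverConfig()) {
    chs <- chains(chainSet)
    n <- length(intervals)
    out <- data.frame(
        mapped = logical(n), reason = NA_character_,
        tName = NA_character_, tStart = NA_integer_, tEnd = NA_integer_,
        tStrand = NA_character_, matchedBases = 0L, matchFrac = 0,
        stringsAsFactors = FALSE)
    chrom <- as.character(seqnames(intervals))
    s0 <- start(intervals) - 1L   # 0-based half-open
    e0 <- end(intervals)
    for (i in seq_len(n)) {
        w <- e0[i] - s0[i]
        res <- list()
        for (ch in chs) {
            if (ch$sName != chrom[i]) next
            os <- pmax(s0[i], ch$blockSrcStart)
            oe <- pmin(e0[i], ch$blockSrcEnd)
            len <- oe - os
            keep <- len > 0L
            if (!any(keep)) next
            res[[length(res) + 1L]] <- list(ch = ch, os = os[keep],
                                            oe = oe[keep],
                                            bi = which(keep),
                                            bases = sum(len[keep]))
        }
        if (!length(res)) { out$reason[i] <- "no_chain"; next }
        if (length(res) > 1L && !config@allowMultiple) {
            out$reason[i] <- "split_across_chains"; next
        }
        best <- res[[which.max(vapply(res, `[[`, numeric(1), "bases"))]]
        frac <- best$bases / w
        out$matchedBases[i] <- best$bases
        out$matchFrac[i] <- frac
        if (frac < config@minMatch) {
            out$reason[i] <- "below_min_match"; next
        }
        ch <- best$ch
        # target positions of the mapped bases, in the chain's own target
        # coordinate space (strand convention of the file)
        ts <- ch$blockTgtStart[best$bi] + (best$os - ch$blockSrcStart[best$bi])
        te <- ch$blockTgtStart[best$bi] + (best$oe - ch$blockSrcStart[best$bi])
        qs <- min(ts); qe <- max(te)
        if (ch$tStrand == "-") {
            fs <- ch$tSize - qe
            fe <- ch$tSize - qs
        } else {
            fs <- qs; fe <- qe
        }
        out$mapped[i] <- TRUE
        out$tName[i] <- ch$tName
        out$tStart[i] <- fs + 1L   # back to 1-based closed
        out$tEnd[i] <- fe
        out$tStrand[i] <- ch$tStrand
    }
    out
}

#' Three-way conservation classification of standardized elements
#'
#' Elements that fail to map are un-conserved; mapped elements overlapping
#' (>= 1 bp) a target element of the same class are functionally conserved;
#' mapped elements without such an overlap are sequence-only conserved.
#' Elements are expected in their standardized (summit-centred 2 kb) form
#' and target elements classified by the same annotation rules.
#'
#' @param elements GRanges with an \code{elementClass} column, source
#'   coordinates.
#' @param chainSet a \code{\link{ChainSet}}.
#' @param targetElements GRanges with \code{elementClass}, target
#'   coordinates.
#' @param config a \code{\link{LiftOverConfig}}.
#' @return data.frame: element \code{name}, \code{elementClass},
#'   \code{status} in \{un_conserved, sequence_only, functional\}, target
#'   coordinates for mapped elements, \code{reason} for unmapped ones and
#'   the matched target element names.
#' @export
classifyConservation <- function(elements, chainSet, targetElements,
                                 config = LiftOverConfig()) {
    if (is.null(elements$elementClass))
        stopf("elements need an 'elementClass' column")
    mp <- mapIntervals(elements, chainSet, config)
    status <- rep("un_conserved", length(elements))
    matchedTarget <- rep(NA_character_, length(elements))
    mappedIdx <- which(mp$mapped)
    missingClasses <- setdiff(unique(elements$elementClass[mappedIdx]),
                              unique(targetElements$elementClass))
    if (length(missingClasses))
        warnf("element class(es) %s absent from target set; mapped elements of those classes become sequence_only",
              paste(missingClasses, collapse = ", "))
    if (length(mappedIdx)) {
        tgt <- GRanges(mp$tName[mappedIdx],
                       IRanges(mp$tStart[mappedIdx], mp$tEnd[mappedIdx]))
        hits <- findOverlaps(tgt, targetElements, ignore.strand = TRUE)
        sameClass <- elements$elementClass[mappedIdx][queryHits(hits)] ==
            targetElements$elementClass[subjectHits(hits)]
        hits <- hits[sameClass]
        status[mappedIdx] <- "sequence_only"
        fun <- unique(queryHits(hits))
        status[mappedIdx[fun]] <- "functional"
        firstHit <- !duplicated(queryHits(hits))
        matchedTarget[mappedIdx[queryHits(hits)[firstHit]]] <-
            if (!is.null(targetElements$name))
                targetElements$name[subjectHits(hits)[firstHit]]
            else as.character(subjectHits(hits)[firstHit])
    }
    data.frame(
        name = if (!is.null(elements$name)) elements$name
               else sprintf("el%d", seq_along(elements)),
        elementClass = elements$elementClass,
        status = status,
        reason = mp$reason,
        tName = mp$tName, tStart = mp$tStart, tEnd = mp$tEnd,
        tStrand = mp$tStrand, matchFrac = mp$matchFrac,
        matchedTarget = matchedTarget,
        stringsAsFactors = FALSE)
}

#' Distance from element midpoints to the nearest TSS
#'
#' @param elements GRanges.
#' @param tss GRanges of TSS positions.
#' @return integer vector of bp distances (0 when the midpoint coincides
#'   with a TSS).
#' @export
distanceToNearestGene <- function(elements, tss) {
    if (length(tss) == 0L) stopf("empty TSS set")
    mid <- grMid(elements)
    chrom <- as.character(seqnames(elements))
    tchrom <- as.character(seqnames(tss))
    out <- rep(NA_integer_, length(elements))
    for (cc in unique(chrom)) {
        ei <- which(chrom == cc)
        pos <- sort(start(tss)[tchrom == cc])
        if (!length(pos)) next
        idx <- findInterval(mid[ei], pos)
        left <- ifelse(idx >= 1L, abs(mid[ei] - pos[pmax(idx, 1L)]), Inf)
        right <- ifelse(idx < length(pos),
                        abs(pos[pmin(idx + 1L, length(pos))] - mid[ei]), Inf)
        out[ei] <- as.integer(pmin(left, right))
    }
    if (anyNA(out))
        stopf("some elements lie on chromosomes with no TSS")
    out
}

#' Two-sample KS comparison with a random-draw control band
#'
#' Compares two distance distributions by a two-sample Kolmogorov-Smirnov
#' test and, alongside, draws \code{nDraws} random subsets of
#' \code{drawSize} elements (without replacement within a draw, with
#' replacement across draws) from a pool, returning their distance
#' distributions as the control band (100 draws of 4000 by default).
#'
#' @param distancesA,distancesB numeric distance samples.
#' @param poolDistances distances of the full element pool to draw controls
#'   from.
#' @param nDraws,drawSize control-draw geometry.
#' @param seed RNG seed for the draws.
#' @return list with \code{statistic} (KS D), \code{p.value}, and
#'   \code{controls}, a list of \code{nDraws} numeric vectors.
#' @export
ksCompareWithRandomControl <- function(distancesA, distancesB,
                                       poolDistances, nDraws = 100L,
                                       drawSize = 4000L, seed = 1L) {
    if (!length(distancesA) || !length(distancesB))
        stopf("both samples must be non-empty")
    if (drawSize > length(poolDistances))
        stopf("drawSize (%d) exceeds pool size (%d) and within-draw sampling is without replacement",
              drawSize, length(poolDistances))
    ks <- suppressWarnings(stats::ks.test(distancesA, distancesB))
    controls <- withChildSeed(seed, 0L, {
        lapply(seq_len(nDraws), function(i)
            poolDistances[sample.int(length(poolDistances), drawSize,
                                     replace = FALSE)])
    })
    list(statistic = unname(ks$statistic), p.value = ks$p.value,
         controls = controls)
}

#' Overlay chromatin states onto mapped elements
#'
#' For each element and tissue, the state segment with the largest overlap
#' determines the element's state category in that tissue (ties break to
#' the first segment in genome order; elements covered by no segment in a
#' tissue get "other"). An element counts as regulatory in a tissue when
#' its category is primary_DNase, weak_enhancer or active_enhancer.
#'
#' @param elements GRanges in target-genome coordinates (e.g. mapped
#'   sequence-only conserved elements).
#' @param segments GRanges with \code{state} and \code{tissue} columns.
#' @param categoryMap named character vector, state label -> category in
#'   \{primary_DNase, weak_enhancer, active_enhancer, other\}.
#' @return list: \code{matrix} (character, elements x tissues),
#'   \code{perCategory} (table of cell counts), \code{perTissue} (number of
#'   regulatory elements per tissue), \code{regulatoryAny} (logical per
#'   element: regulatory in >= 1 tissue), \code{nRegulatoryAny}.
#' @export
overlayChromatinStates <- function(elements, segments, categoryMap) {
    tissues <- sort(unique(segments$tissue))
    regCats <- c("primary_DNase", "weak_enhancer", "active_enhancer")
    mat <- matrix("other", nrow = length(elements), ncol = length(tissues),
                  dimnames = list(NULL, tissues))
    for (j in seq_along(tissues)) {
        seg <- segments[segments$tissue == tissues[j]]
        hits <- findOverlaps(elements, seg, ignore.strand = TRUE)
        if (!length(hits)) next
        ov <- width(pintersect(elements[queryHits(hits)],
                               seg[subjectHits(hits)]))
        # largest overlap wins per element
        ord <- order(queryHits(hits), -ov, subjectHits(hits))
        pick <- !duplicated(queryHits(hits)[ord])
        qi <- queryHits(hits)[ord][pick]
        si <- subjectHits(hits)[ord][pick]
        cat <- categoryMap[seg$state[si]]
        cat[is.na(cat)] <- "other"
        mat[qi, j] <- cat
    }
    isReg <- matrix(mat %in% regCats, nrow = nrow(mat))
    list(matrix = mat,
         perCategory = table(factor(mat, levels = c(regCats, "other"))),
         perTissue = stats::setNames(colSums(isReg), tissues),
         regulatoryAny = rowSums(isReg) > 0L,
         nRegulatoryAny = sum(rowSums(isReg) > 0L))
}

#' k-means clustering of a chromatin-state matrix
#'
#' One-hot encodes the category matrix and runs standard k-means (fixed
#' seed, fixed iteration cap; k = 100 by default, matching the row
#' clustering used to display state profiles). Cluster ids are renumbered
#' by size, largest first.
#'
#' @param mat character matrix (elements x tissues) of state categories.
#' @param k number of clusters (must not exceed the number of rows).
#' @param seed RNG seed.
#' @return integer vector of cluster assignments (1 = largest cluster).
#' @export
clusterStateMatrix <- function(mat, k = 100L, seed = 1L) {
    if (k > nrow(mat))
        stopf("k (%d) exceeds the number of elements (%d)", k, nrow(mat))
    lev <- sort(unique(as.vector(mat)))
    enc <- do.call(cbind, lapply(seq_len(ncol(mat)), function(j)
        outer(mat[, j], lev, `==`) * 1))
    nDistinct <- nrow(unique(enc))
    if (k > nDistinct)
        stopf("k (%d) exceeds the number of distinct state patterns (%d)",
              k, nDistinct)
    if (k == nrow(mat))         # every element its own cluster
        return(seq_len(k))
    cl <- withChildSeed(seed, 0L,
        stats::kmeans(enc, centers = k, iter.max = 100L, nstart = 1L))
    sizes <- table(cl$cluster)
    newId <- stats::setNames(rank(-as.numeric(sizes), ties.method = "first"),
                             names(sizes))
    as.integer(newId[as.character(cl$cluster)])
}
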