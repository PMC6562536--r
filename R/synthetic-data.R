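# Seeded generators for every input the pipeline consumes, with planted
# ground truth: conservation fractions, super-enhancer signal geometry,
# expression effects. Child seeds are derived from the master seed by fixed
# offsets, so each generator is reproducible and independent of call order.

SEED_REFERENCE <- 101L
SEED_PEAKS <- 202L
SEED_CHAIN <- 303L
SEED_PWM <- 404L
SEED_STATES <- 505L
SEED_CRC <- 606L

#' Generate a synthetic reference bundle
#'
#' Produces chromosome sizes, an (optional) random genome sequence,
#' non-overlapping gene models laid out on a per-chromosome grid with
#' strand-consistent TSS, and a two-replicate TPM expression table. The
#' grid guarantees genes never overlap and leaves room for promoter-scale
#' peaks around every TSS; a chromosome too short for its share of genes is
#' a sizing error.
#'
#' @param config a \code{\link{SyntheticConfig}}.
#' @param withSequence generate the genome sequence (skip for large
#'   coordinate-only simulations).
#' @return list: \code{seqinfo}, \code{genome} (DNAStringSet or NULL),
#'   \code{genes} (GRanges with gene_id), \code{tss} (width-1 GRanges),
#'   \code{expression} (genes x 2 TPM matrix), \code{slotWidth}.
#' @export
generateReference <- function(config = SyntheticConfig(),
                              withSequence = TRUE) {
    validObject(config)
    si <- Seqinfo(seqnames = sprintf("chr%d", seq_len(config@nChroms)),
                  seqlengths = rep(config@chromLen, config@nChroms))
    withChildSeed(config@seed, SEED_REFERENCE, {
        genome <- NULL
        if (withSequence) {
            genome <- Biostrings::DNAStringSet(vapply(
                seq_len(config@nChroms),
                function(i) paste(sample(c("A", "C", "G", "T"),
                                         config@chromLen, replace = TRUE),
                                  collapse = ""),
                character(1)))
            names(genome) <- GenomeInfoDb::seqnames(si)
        }
        nG <- config@nGenes
        if (nG == 0L) {
            genes <- GRanges()
            genes$gene_id <- character()
            expr <- matrix(numeric(), 0L, 2L,
                           dimnames = list(NULL, c("rep1", "rep2")))
            return(list(seqinfo = si, genome = genome, genes = genes,
                        tss = tssFromGenes(genes, genes$gene_id),
                        expression = expr, slotWidth = NA_integer_))
        }
        per <- rep(nG %/% config@nChroms, config@nChroms)
        extra <- nG %% config@nChroms
        if (extra) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
        slotW <- as.integer(config@chromLen %/% max(per))
        if (slotW < 2400L)
            stopf("chromosome length %d too short for %d genes per chromosome (need slots >= 2400 bp)",
                  config@chromLen, max(per))
        gl <- list()
        for (i in seq_len(config@nChroms)) {
            if (per[i] == 0L) next
            slotStart <- (seq_len(per[i]) - 1L) * slotW + 1L
            maxLen <- min(8000L, slotW - 300L)
            len <- as.integer(round(stats::runif(per[i], 2000L, maxLen)))
            off <- vapply(slotW - len - 100L, function(m)
                as.integer(round(stats::runif(1L, 50L, m))), integer(1))
            s <- slotStart + off
            gr <- GRanges(GenomeInfoDb::seqnames(si)[i],
                          IRanges(s, s + len - 1L),
                          strand = sample(c("+", "-"), per[i],
                                          replace = TRUE))
            gl[[i]] <- gr
        }
        genes <- suppressWarnings(do.call(c, gl[!vapply(gl, is.null,
                                                        logical(1))]))
        seqinfo(genes) <- si
        genes$gene_id <- sprintf("g%05d", seq_along(genes))
        base <- stats::rlnorm(length(genes), meanlog = 1.5, sdlog = 1.2)
        expr <- cbind(rep1 = base,
                      rep2 = base * 2^stats::rnorm(length(genes), 0, 0.1))
        rownames(expr) <- genes$gene_id
        list(seqinfo = si, genome = genome, genes = genes,
             tss = tssFromGenes(genes, genes$gene_id),
             expression = expr, slotWidth = slotW)
    })
}

# carve non-overlapping placement slots of slotW bp out of the genome
# complement of the avoided regions
distalSlots <- function(si, avoid, slotW) {
    full <- GRanges(GenomeInfoDb::seqnames(si),
                    IRanges(1L, seqlengths(si)))
    seqinfo(full) <- si
    free <- GenomicRanges::setdiff(full, avoid, ignore.strand = TRUE)
    free <- free[width(free) >= slotW]
    sl <- lapply(seq_along(free), function(i) {
        n <- width(free)[i] %/% slotW
        s <- start(free)[i] + (seq_len(n) - 1L) * slotW
        GRanges(seqnames(free)[i], IRanges(s, s + slotW - 1L))
    })
    out <- suppressWarnings(do.call(c, sl))
    seqinfo(out) <- si
    out
}

#' Generate peak sets and matching coverage tracks
#'
#' Plants the structure downstream classification relies on: a configured
#' fraction of H3K4me3 peaks inside TSS windows (a slice of them wide
#' enough to be broad domains), a configured fraction of H3K27ac peaks
#' TSS-distal with Pareto(\code{seTailExponent}) heavy-tailed signal (so a
#' super-enhancer elbow exists), and the remaining H3K27ac peaks on top of
#' promoters (active-promoter planting). Coverage is emitted at 10 bp
#' resolution with per-peak read totals equal to the recorded RPM (library
#' size fixed at 1e6), perturbed multiplicatively by \code{noiseSd} — so at
#' noiseSd = 0 recomputing RPM from coverage reproduces the peak records
#' exactly. Genes nearest the strongest distal enhancers get their
#' expression boosted by \code{deEffectLog2} log2 units (the
#' super-enhancer-linked expression planting).
#'
#' @param config a \code{\link{SyntheticConfig}}.
#' @param ref output of \code{\link{generateReference}}.
#' @param withCoverage build coverage tracks (skip for large
#'   coordinate-only simulations).
#' @return list: \code{h3k4me3}, \code{h3k27ac} (peak GRanges),
#'   \code{ipK4}, \code{ipK27}, \code{input}, \code{ipK4rep1},
#'   \code{ipK4rep2} (CoverageTracks or NULL), \code{expression} (boosted
#'   matrix), \code{seLinkedGenes} (gene ids with the planted boost).
#' @export
generatePeaksAndCoverage <- function(config = SyntheticConfig(), ref,
                                     withCoverage = TRUE) {
    validObject(config)
    si <- ref$seqinfo
    tss <- ref$tss
    anno <- AnnotationConfig()
    withChildSeed(config@seed, SEED_PEAKS, {
        nG <- length(ref$genes)
        n4tss <- min(round(config@fracK4AtTss * config@nH3K4me3), nG)
        n4dist <- config@nH3K4me3 - n4tss
        n27dist <- round(config@fracK27Distal * config@nH3K27ac)
        n27prom <- config@nH3K27ac - n27dist

        # --- H3K4me3 at TSS: one peak per sampled gene, kept inside the
        # gene's slot so same-mark peaks never overlap
        k4 <- GRanges(); k4kind <- character()
        if (n4tss > 0L) {
            gi <- sort(sample.int(nG, n4tss))
            pos <- start(tss)[gi]
            slotW <- ref$slotWidth
            slotStart <- ((pos - 1L) %/% slotW) * slotW + 1L
            broad <- stats::runif(n4tss) < 0.15
            w <- ifelse(broad,
                        round(stats::runif(n4tss, 4200, min(7500, slotW - 600))),
                        round(stats::runif(n4tss, 800, 3000)))
            s <- pmax(pos - as.integer(w %/% 2L), slotStart + 60L)
            e <- pmin(s + w - 1L, slotStart + slotW - 60L)
            k4 <- GRanges(seqnames(tss)[gi], IRanges(s, e))
            k4kind <- rep("tss", n4tss)
            k4$gene <- tss$gene_id[gi]
        }

        # --- shared distal slot pool, avoiding (padded) TSS windows
        win <- tssWindows(tss, anno)
        pad <- GRanges(seqnames(win),
                       IRanges(pmax(start(win) - 100L, 1L),
                               pmin(end(win) + 100L,
                                    seqlengths(si)[as.character(seqnames(win))])))
        slots <- distalSlots(si, pad, 4600L)
        need <- n4dist + n27dist
        if (length(slots) < need)
            stopf("genome too small: %d distal slots available, %d needed",
                  length(slots), need)
        pick <- sort(sample.int(length(slots), need))
        useSlot <- function(idx, widths) {
            sl <- slots[pick[idx]]
            off <- as.integer(round(stats::runif(length(idx), 1200L,
                                                 4600L - 1200L - widths)))
            GRanges(seqnames(sl), IRanges(start(sl) + off,
                                          start(sl) + off + widths - 1L))
        }
        if (n4dist > 0L) {
            w <- as.integer(round(stats::runif(n4dist, 800, 2000)))
            k4d <- useSlot(seq_len(n4dist), w)
            k4d$gene <- NA_character_
            k4 <- c(k4, k4d)
            k4kind <- c(k4kind, rep("distal", n4dist))
        }
        k27 <- GRanges(); k27kind <- character()
        if (n27dist > 0L) {
            w <- as.integer(round(stats::runif(n27dist, 600, 2000)))
            k27 <- useSlot(n4dist + seq_len(n27dist), w)
            k27$gene <- NA_character_
            k27kind <- rep("distal", n27dist)
        }
        # --- H3K27ac over promoters (active-promoter planting); genes with
        # higher expression are more likely to get the H3K27ac peak, so
        # active promoters sit on better-expressed genes than poised ones
        if (n27prom > 0L && n4tss > 0L) {
            wExpr <- ref$expression[k4$gene[seq_len(n4tss)], "rep1"] + 0.1
            gi <- sample.int(n4tss, min(n27prom, n4tss), prob = wExpr)
            base <- k4[gi]
            w <- as.integer(round(stats::runif(length(gi), 600, 1500)))
            s <- pmax(start(base) + 10L,
                      grMid(base) - as.integer(w %/% 2L))
            k27p <- GRanges(seqnames(base), IRanges(s, s + w - 1L))
            k27p$gene <- base$gene
            k27 <- c(k27, k27p)
            k27kind <- c(k27kind, rep("promoter", length(gi)))
        }
        seqinfo(k4) <- si; seqinfo(k27) <- si

        decorate <- function(gr, kind, mark) {
            n <- length(gr)
            enhLike <- kind == "distal" & mark == "H3K27ac"
            rpmIP <- ifelse(enhLike,
                            5 * stats::runif(n)^(-1 / config@seTailExponent),
                            stats::rlnorm(n, meanlog = log(10), sdlog = 0.5))
            weak <- stats::runif(n) < 0.05
            rpmInput <- ifelse(weak, rpmIP / 1.6,
                               rpmIP / stats::runif(n, 3, 8))
            noisy <- stats::runif(n) < 0.07
            pval <- ifelse(noisy, stats::runif(n, 0.011, 0.5),
                           10^(-stats::runif(n, 3, 30)))
            third <- pmax(width(gr) %/% 3L, 1L)
            gr$summit <- start(gr) + third +
                as.integer(floor(stats::runif(n) * third))
            gr$rpmIP <- rpmIP
            gr$rpmInput <- rpmInput
            gr$pvalue <- pval
            gr$mark <- mark
            gr$kind <- kind
            gr$name <- sprintf("%s_%05d", tolower(mark), seq_len(n))
            gr
        }
        k4 <- decorate(k4, k4kind, "H3K4me3")
        k27 <- decorate(k27, k27kind, "H3K27ac")

        # --- SE-linked expression planting: boost genes nearest the
        # strongest distal enhancers
        expr <- ref$expression
        seLinked <- character()
        distIdx <- which(k27$kind == "distal")
        if (length(distIdx) >= 20L && nrow(expr) > 0L) {
            topN <- max(5L, as.integer(round(0.05 * length(distIdx))))
            top <- distIdx[order(-k27$rpmIP[distIdx])][seq_len(topN)]
            seLinked <- unique(linkElementsToGenes(k27[top], tss))
            expr[seLinked, ] <- expr[seLinked, ] * 2^config@deEffectLog2
        }

        tracks <- list(ipK4 = NULL, ipK27 = NULL, input = NULL,
                       ipK4rep1 = NULL, ipK4rep2 = NULL)
        if (withCoverage) {
            tracks$ipK4 <- peaksToTrack(k4, k4$rpmIP, si, config@noiseSd)
            tracks$ipK27 <- peaksToTrack(k27, k27$rpmIP, si, config@noiseSd)
            tracks$input <- peaksToTrack(c(granges(k4), granges(k27)),
                                         c(k4$rpmInput, k27$rpmInput),
                                         si, config@noiseSd)
            tracks$ipK4rep1 <- peaksToTrack(
                k4, k4$rpmIP / 2 * (1 + stats::rnorm(length(k4), 0, 0.05)),
                si, config@noiseSd)
            tracks$ipK4rep2 <- peaksToTrack(
                k4, k4$rpmIP / 2 * (1 + stats::rnorm(length(k4), 0, 0.05)),
                si, config@noiseSd)
        }
        c(list(h3k4me3 = k4, h3k27ac = k27, expression = expr,
               seLinkedGenes = seLinked), tracks)
    })
}

#' @importFrom GenomicRanges granges
peaksToTrack <- function(peaks, reads, si, noiseSd = 0, binSize = 10L) {
    total <- pmax(reads * (1 + stats::rnorm(length(peaks), 0, noiseSd)), 0)
    w <- width(peaks)
    nPieces <- (w + binSize - 1L) %/% binSize
    idx <- rep(seq_along(peaks), nPieces)
    off <- (sequence(nPieces) - 1L) * binSize
    s <- start(peaks)[idx] + off
    e <- pmin(s + binSize - 1L, end(peaks)[idx])
    cov <- GRanges(seqnames(peaks)[idx], IRanges(s, e))
    cov$score <- total[idx] * (e - s + 1) / w[idx]
    cov <- GenomicRanges::sort(cov)
    seqinfo(cov) <- si
    CoverageTrack(cov = cov, totalReads = 1e6, binSize = binSize)
}

#' Generate a target genome, alignment chains and target elements with
#' planted conservation status
#'
#' Each source element is assigned a conservation status by a seeded draw
#' with exact planted counts at the configured fractions
#' (\code{fracFunctional}, \code{fracSequenceOnly}, remainder
#' un-conserved); with \code{distanceBias} (the default), functional status
#' goes preferentially to elements near genes, reproducing the
#' closer-to-genes distribution of functionally conserved enhancers.
#' Chains are then constructed so that
#' un-conserved elements fall entirely in alignment gaps, while conserved
#' elements sit inside aligned blocks; small insertions and deletions are
#' interleaved between elements, and the last chromosome's chain is emitted
#' on the '-' target strand (coordinates in UCSC reverse-complement
#' convention). Functionally conserved elements get a same-class target
#' element at their mapped position; a minority of sequence-only elements
#' get an overlapping element of a different class (decoys). Genes whose
#' TSS lies in an aligned block become one-to-one orthologs; a tenth of
#' them receive a planted expression shift of \code{deEffectLog2} log2
#' units (half up, half down) in the target species.
#'
#' @param config a \code{\link{SyntheticConfig}}.
#' @param ref output of \code{\link{generateReference}}.
#' @param elements GRanges with \code{elementClass} (and \code{name}),
#'   non-overlapping with gaps >= 150 bp and >= 200 bp from chromosome
#'   ends; defaults to 2 kb windows around every gene TSS with class
#'   "promoter".
#' @param distanceBias plant functional status preferentially near genes.
#' @return list: \code{chainSet}, \code{targetSeqinfo},
#'   \code{targetElements}, \code{plantedStatus} (character per element),
#'   \code{orthology} (data.frame gene_source/gene_target/homology_type),
#'   \code{targetGenes}, \code{targetTss}, \code{sourceExpression},
#'   \code{targetExpression}, \code{deTable} (gene_id, log2_fold, pvalue),
#'   \code{deTruth} (planted direction per ortholog).
#' @export
generateChainPair <- function(config = SyntheticConfig(), ref,
                              elements = NULL, distanceBias = TRUE) {
    validObject(config)
    si <- ref$seqinfo
    if (is.null(elements)) {
        e0 <- ref$tss
        half <- 1000L
        sl <- seqlengths(si)[as.character(seqnames(e0))]
        elements <- GRanges(seqnames(e0),
                            IRanges(pmax(start(e0) - half, 201L),
                                    pmin(start(e0) + half - 1L, sl - 200L)))
        elements$elementClass <- "promoter"
        elements$name <- e0$gene_id
        seqinfo(elements) <- si
    }
    if (is.null(elements$name))
        elements$name <- sprintf("el%05d", seq_along(elements))
    ord <- order(as.character(seqnames(elements)), start(elements))
    srt <- elements[ord]
    bychr <- split(seq_along(srt), as.character(seqnames(srt)))
    for (ii in bychr) {
        if (length(ii) > 1L) {
            gaps <- start(srt)[ii][-1L] - end(srt)[ii][-length(ii)] - 1L
            if (any(gaps < 150L))
                stopf("elements must be separated by >= 150 bp for chain planting")
        }
        sl <- seqlengths(si)[as.character(seqnames(srt))[ii]]
        if (any(start(srt)[ii] < 200L) || any(end(srt)[ii] > sl - 200L))
            stopf("elements must lie >= 200 bp from chromosome ends for chain planting")
    }
    withChildSeed(config@seed, SEED_CHAIN, {
        # planted status: exact counts at the configured fractions; when
        # distanceBias is on, functional status goes preferentially to
        # elements near genes (the genomic-distribution signature of
        # functionally conserved enhancers)
        n <- length(srt)
        nFun <- round(config@fracFunctional * n)
        nSeq <- round(config@fracSequenceOnly * n)
        status <- rep("un_conserved", n)
        if (distanceBias && length(ref$tss)) {
            d <- distanceToNearestGene(srt, ref$tss)
            w <- exp(-3 * rank(d, ties.method = "first") / max(n, 1L))
            funIdx <- sample.int(n, nFun, prob = w)
        } else {
            funIdx <- sample.int(n, nFun)
        }
        status[funIdx] <- "functional"
        rest <- setdiff(seq_len(n), funIdx)
        status[sample(rest, nSeq)] <- "sequence_only"
        chroms <- GenomeInfoDb::seqnames(si)
        recs <- list()
        tgtElems <- list()
        tgtSizes <- integer(length(chroms))
        geneImage <- list()
        margin <- 50L
        for (ci in seq_along(chroms)) {
            cc <- chroms[ci]
            L <- seqlengths(si)[[cc]]
            ii <- bychr[[cc]]
            es <- if (is.null(ii)) integer() else start(srt)[ii] - 1L # 0-based
            ee <- if (is.null(ii)) integer() else end(srt)[ii]
            stat <- if (is.null(ii)) character() else status[ii]
            # breaks: (srcPos, dt, dq), in increasing srcPos
            bp <- integer(); bdt <- integer(); bdq <- integer()
            prev <- 0L
            indelKind <- 0L
            for (k in seq_along(es)) {
                gapLen <- es[k] - margin - prev
                if (gapLen > 300L) {  # room for an indel
                    indelKind <- (indelKind + 1L) %% 3L
                    delta <- as.integer(sample(20:80, 1L))
                    if (indelKind == 1L) {          # insertion in target
                        bp <- c(bp, prev + 100L); bdt <- c(bdt, 0L)
                        bdq <- c(bdq, delta)
                    } else if (indelKind == 2L) {   # deletion from target
                        bp <- c(bp, prev + 100L); bdt <- c(bdt, delta)
                        bdq <- c(bdq, 0L)
                    }
                }
                if (stat[k] == "un_conserved") {
                    bp <- c(bp, es[k] - margin)
                    bdt <- c(bdt, (ee[k] + margin) - (es[k] - margin))
                    bdq <- c(bdq, 0L)
                }
                prev <- ee[k] + margin
            }
            # assemble blocks over [0, L)
            starts <- c(0L, bp + bdt)
            ends <- c(bp, L)
            size <- ends - starts
            keep <- size > 0L
            size <- size[keep]
            dt <- bdt; dq <- bdq
            if (any(!keep))
                stopf("internal: degenerate chain block on %s", cc)
            tSize <- L - sum(dt) + sum(dq)
            tgtSizes[ci] <- tSize
            tStrandOut <- if (ci == length(chroms) && length(chroms) > 1L)
                "-" else "+"
            rec <- chainRecord(
                id = as.character(ci), score = 1000,
                sName = cc, sSize = L, sStart = 0L, sEnd = L,
                tName = paste0("t_", cc), tSize = tSize,
                tStrand = tStrandOut, tStart = 0L, tEnd = tSize,
                size = size, dt = dt, dq = dq)
            recs[[ci]] <- rec
            # map a source position through this chain (chain target space)
            mapPos <- function(p) {
                bi <- findInterval(p, rec$blockSrcStart)
                if (bi < 1L || p >= rec$blockSrcEnd[bi]) return(NA_integer_)
                rec$blockTgtStart[bi] + (p - rec$blockSrcStart[bi])
            }
            toFwd <- function(q0s, q0e) {   # chain-space [q0s,q0e) -> fwd
                if (tStrandOut == "-") c(tSize - q0e, tSize - q0s)
                else c(q0s, q0e)
            }
            # target elements at the images of conserved elements
            for (k in seq_along(es)) {
                if (stat[k] == "un_conserved") next
                q0s <- mapPos(es[k]); q0e <- mapPos(ee[k] - 1L)
                if (is.na(q0s) || is.na(q0e)) next
                fw <- toFwd(min(q0s, q0e), max(q0s, q0e) + 1L)
                cls <- srt$elementClass[ii[k]]
                if (stat[k] == "functional") {
                    gr <- GRanges(paste0("t_", cc),
                                  IRanges(fw[1L] + 1L, fw[2L]))
                    gr$elementClass <- cls
                    gr$name <- paste0("t_", srt$name[ii[k]])
                    tgtElems[[length(tgtElems) + 1L]] <- gr
                } else if (stats::runif(1) < 0.2) {
                    # decoy of a different class over a fifth of the
                    # sequence-only elements
                    gr <- GRanges(paste0("t_", cc),
                                  IRanges(fw[1L] + 1L, fw[2L]))
                    gr$elementClass <- if (cls == "enhancer")
                        "active_promoter" else "enhancer"
                    gr$name <- paste0("decoy_", srt$name[ii[k]])
                    tgtElems[[length(tgtElems) + 1L]] <- gr
                }
            }
            # gene images for orthology
            gOnC <- which(as.character(seqnames(ref$genes)) == cc)
            if (length(gOnC)) {
                tpos <- vapply(start(ref$tss)[gOnC] - 1L, mapPos,
                               integer(1))
                okg <- !is.na(tpos)
                fwd <- ifelse(rep(tStrandOut, length(tpos)) == "-",
                              tgtSizes[ci] - 1L - tpos, tpos)
                geneImage[[cc]] <- data.frame(
                    idx = gOnC[okg],
                    tchrom = paste0("t_", cc),
                    tpos = fwd[okg] + 1L,
                    flip = tStrandOut == "-")
            }
        }
        tgtSi <- Seqinfo(seqnames = paste0("t_", as.character(chroms)),
                         seqlengths = tgtSizes)
        tgtElemGr <- if (length(tgtElems))
            suppressWarnings(do.call(c, tgtElems)) else GRanges()
        if (length(tgtElemGr)) seqinfo(tgtElemGr) <- tgtSi
        chainSet <- ChainSet(chains = recs, sourceSeqinfo = si,
                             targetSeqinfo = tgtSi)

        # orthology + target genes + planted DE
        gi <- do.call(rbind, geneImage)
        orthology <- data.frame(gene_source = character(),
                                gene_target = character(),
                                homology_type = character())
        targetGenes <- GRanges(); targetTss <- GRanges()
        deTable <- NULL; deTruth <- NULL
        srcExpr <- ref$expression
        tgtExpr <- NULL
        if (!is.null(gi) && nrow(gi)) {
            srcIds <- ref$genes$gene_id[gi$idx]
            tgtIds <- paste0("t_", srcIds)
            orthology <- data.frame(gene_source = srcIds,
                                    gene_target = tgtIds,
                                    homology_type = "one2one")
            st <- as.character(strand(ref$genes))[gi$idx]
            st <- ifelse(gi$flip, ifelse(st == "+", "-", "+"), st)
            targetTss <- GRanges(gi$tchrom, IRanges(gi$tpos, width = 1L),
                                 strand = st)
            targetTss$gene_id <- tgtIds
            seqinfo(targetTss) <- tgtSi
            nOrth <- nrow(gi)
            nDe <- max(1L, as.integer(round(0.1 * nOrth)))
            deIdx <- sample.int(nOrth, nDe)
            dirUp <- seq_along(deIdx) <= ceiling(nDe / 2)
            effect <- rep(0, nOrth)
            effect[deIdx] <- ifelse(dirUp, config@deEffectLog2,
                                    -config@deEffectLog2)
            noise <- stats::rnorm(nOrth, 0, 0.2)
            noise[deIdx] <- 0
            srcTpm <- srcExpr[srcIds, "rep1"]
            # effect is expressed as source-over-target fold change
            tgtTpm <- srcTpm * 2^(-(effect + noise))
            tgtExpr <- cbind(
                rep1 = tgtTpm,
                rep2 = tgtTpm * 2^stats::rnorm(nOrth, 0, 0.1))
            rownames(tgtExpr) <- tgtIds
            pv <- stats::runif(nOrth, 0.0015, 1)
            pv[deIdx] <- 10^(-stats::runif(nDe, 4, 25))
            deTable <- data.frame(gene_id = srcIds,
                                  log2_fold = effect + noise,
                                  pvalue = pv)
            truth <- rep("ns", nOrth)
            truth[deIdx] <- ifelse(dirUp, "up_in_A", "down_in_A")
            deTruth <- data.frame(gene_id = srcIds, direction = truth)
        }
        plantedStatus <- status[order(ord)]  # back to input order
        list(chainSet = chainSet, targetSeqinfo = tgtSi,
             targetElements = tgtElemGr, plantedStatus = plantedStatus,
             orthology = orthology, targetTss = targetTss,
             sourceExpression = srcExpr, targetExpression = tgtExpr,
             deTable = deTable, deTruth = deTruth)
    })
}

#' Identity chain set for a genome
#'
#' One full-length, gap-free chain per chromosome mapping every base to
#' itself (optionally onto renamed target chromosomes). Useful as the
#' degenerate case of chain-based mapping.
#'
#' @param si a Seqinfo.
#' @param targetPrefix prefix for target chromosome names.
#' @return a \code{\link{ChainSet}}.
#' @export
identityChainSet <- function(si, targetPrefix = "") {
    nm <- GenomeInfoDb::seqnames(si)
    recs <- lapply(seq_along(nm), function(i) {
        L <- seqlengths(si)[[i]]
        chainRecord(id = as.character(i), score = 1000,
                    sName = nm[i], sSize = L, sStart = 0L, sEnd = L,
                    tName = paste0(targetPrefix, nm[i]), tSize = L,
                    tStrand = "+", tStart = 0L, tEnd = L,
                    size = L, dt = integer(), dq = integer())
    })
    tgtSi <- Seqinfo(seqnames = paste0(targetPrefix, nm),
                     seqlengths = unname(seqlengths(si)))
    ChainSet(chains = recs, sourceSeqinfo = si, targetSeqinfo = tgtSi)
}

#' Generate a PWM collection with planted consensus motifs
#'
#' One near-deterministic PWM per TF: the consensus base carries all the
#' probability mass before pseudocount renormalization, so planted exact
#' occurrences of the consensus are retrievable by string match and score
#' close to the PWM's maximum.
#'
#' @param tfNames character vector of TF names (non-empty).
#' @param seed RNG seed.
#' @param width motif width.
#' @param pseudocount pseudocount for renormalization.
#' @return list: \code{pwms} (named list of probability matrices),
#'   \code{consensus} (named character vector).
#' @export
generatePWMSet <- function(tfNames, seed = 1L, width = 10L,
                           pseudocount = 0.001) {
    if (!length(tfNames)) stopf("tfNames must be non-empty")
    withChildSeed(seed, SEED_PWM, {
        bases <- c("A", "C", "G", "T")
        consensus <- vapply(tfNames, function(tf)
            paste(sample(bases, width, replace = TRUE), collapse = ""),
            character(1))
        pwms <- lapply(consensus, function(cs) {
            idx <- match(strsplit(cs, "")[[1L]], bases)
            m <- matrix(0, width, 4L, dimnames = list(NULL, bases))
            m[cbind(seq_len(width), idx)] <- 1
            normalizePWM(m, pseudocount)
        })
        names(pwms) <- tfNames
        list(pwms = pwms, consensus = consensus)
    })
}

#' Plant motif occurrences into a sequence
#'
#' Overwrites the sequence with \code{motif} at the given start positions
#' (1-based); positions must keep occurrences inside the sequence.
#'
#' @param sequence character string.
#' @param motif character string to plant.
#' @param positions integer start positions.
#' @return the modified sequence.
#' @export
plantMotif <- function(sequence, motif, positions) {
    w <- nchar(motif)
    if (any(positions < 1L | positions + w - 1L > nchar(sequence)))
        stopf("motif occurrence outside sequence bounds")
    for (p in positions)
        substr(sequence, p, p + w - 1L) <- motif
    sequence
}

#' Generate chromatin-state segmentations with planted regulatory elements
#'
#' Builds a per-tissue segmentation of the target genome: the given
#' elements' footprints become their own segments, a planted fraction of
#' elements get a regulatory state (active enhancer, weak enhancer or
#' primary DNase) in at least one tissue — drawn with a bias towards the
#' primary tissue — and everything else is filled with non-regulatory
#' background states.
#'
#' @param elements GRanges (e.g. mapped sequence-only conserved elements),
#'   non-overlapping.
#' @param si Seqinfo of the genome the elements live on.
#' @param seed RNG seed.
#' @param tissues tissue names.
#' @param fracRegulatory fraction of elements regulatory in >= 1 tissue.
#' @param primaryTissue tissue that contributes most regulatory states.
#' @return list: \code{segments} (GRanges with state/tissue),
#'   \code{plantedRegulatory} (logical per element).
#' @export
generateStateSegments <- function(elements, si, seed = 1L,
                                  tissues = c("kidney", "heart", "lung",
                                              "muscle"),
                                  fracRegulatory = 0.782,
                                  primaryTissue = "kidney") {
    withChildSeed(seed, SEED_STATES, {
        regStates <- c("EnhA1", "EnhW1", "DNase")
        bgStates <- c("Quies", "Tx", "ReprPC")
        n <- length(elements)
        planted <- stats::runif(n) < fracRegulatory
        segs <- list()
        for (ti in tissues) {
            # which planted elements are regulatory in this tissue
            inTissue <- planted &
                (stats::runif(n) < ifelse(ti == primaryTissue, 0.9, 0.3))
            stateOfEl <- ifelse(inTissue,
                                sample(regStates, n, replace = TRUE),
                                sample(bgStates, n, replace = TRUE))
            for (cc in GenomeInfoDb::seqnames(si)) {
                L <- seqlengths(si)[[cc]]
                ei <- which(as.character(seqnames(elements)) == cc)
                ei <- ei[order(start(elements)[ei])]
                cuts <- c(0L, as.vector(rbind(start(elements)[ei] - 1L,
                                              end(elements)[ei])), L)
                s <- cuts[-length(cuts)] + 1L
                e <- cuts[-1L]
                keep <- e >= s
                isEl <- rep(FALSE, length(s))
                if (length(ei)) isEl[seq_along(ei) * 2L] <- TRUE
                st <- character(length(s))
                st[!isEl] <- sample(bgStates, sum(!isEl), replace = TRUE)
                st[isEl] <- stateOfEl[ei]
                gr <- GRanges(cc, IRanges(s[keep], e[keep]))
                gr$state <- st[keep]
                gr$tissue <- ti
                segs[[length(segs) + 1L]] <- gr
            }
        }
        out <- suppressWarnings(do.call(c, segs))
        seqinfo(out) <- si
        # guarantee every planted element is regulatory somewhere: force the
        # primary tissue for planted elements that missed every draw
        ov <- overlayChromatinStates(elements, out,
                                     defaultStateCategoryMap())
        miss <- which(planted & !ov$regulatoryAny)
        if (length(miss)) {
            hit <- findOverlaps(elements[miss],
                                out[out$tissue == primaryTissue])
            idx <- which(out$tissue == primaryTissue)[subjectHits(hit)]
            out$state[idx] <- "EnhA1"
        }
        list(segments = out, plantedRegulatory = planted)
    })
}

#' Default chromatin-state category map
#'
#' Maps the generator's state labels to the four categories used by the
#' state overlay: active enhancer, weak enhancer, primary DNase, other.
#'
#' @return named character vector.
#' @export
defaultStateCategoryMap <- function() {
    c(EnhA1 = "active_enhancer", EnhW1 = "weak_enhancer",
      DNase = "primary_DNase", Quies = "other", Tx = "other",
      ReprPC = "other")
}

#' Generate a three-species core-regulatory-circuitry scenario
#'
#' Builds per-species candidate TF sets with a planted overlap structure
#' (\code{nShared} TFs present in every species plus species-specific
#' ones), PWMs for all TFs, and super-enhancer constituent sequences in
#' which every species-member TF's consensus is planted — so each species'
#' CRC is a complete mutual graph over its members and the cross-species
#' intersection recovers exactly the shared set.
#'
#' @param seed RNG seed.
#' @param species species names.
#' @param nShared number of TFs present in all species.
#' @param nSpecific integer vector (per species) of specific TF counts.
#' @return list: per-species \code{candidates}, \code{constituentSeqs},
#'   \code{tpm}; plus shared \code{pwms}, \code{consensus},
#'   \code{sharedTFs}.
#' @export
generateCrcScenario <- function(seed = 1L,
                                species = c("pig", "human", "cattle"),
                                nShared = 10L,
                                nSpecific = c(16L, 8L, 8L)) {
    stopifnot(length(nSpecific) == length(species))
    total <- nShared + sum(nSpecific)
    tfs <- sprintf("TF%02d", seq_len(total))
    sharedTFs <- tfs[seq_len(nShared)]
    offs <- nShared + c(0L, cumsum(nSpecific))
    members <- lapply(seq_along(species), function(i)
        c(sharedTFs, tfs[(offs[i] + 1L):offs[i + 1L]]))
    names(members) <- species
    pw <- generatePWMSet(tfs, seed = seed, width = 10L)
    withChildSeed(seed, SEED_CRC, {
        perSpecies <- lapply(species, function(sp) {
            mm <- members[[sp]]
            seqLen <- 40L * length(mm) + 100L
            seqs <- lapply(mm, function(tf) {
                s <- paste(sample(c("A", "C", "G", "T"), seqLen,
                                  replace = TRUE), collapse = "")
                for (j in seq_along(mm))
                    s <- plantMotif(s, pw$consensus[[mm[j]]],
                                    50L + (j - 1L) * 40L)
                s
            })
            names(seqs) <- mm
            list(candidates = mm, constituentSeqs = seqs,
                 tpm = stats::setNames(rep(10, length(mm)), mm))
        })
        names(perSpecies) <- species
        list(species = perSpecies, pwms = pw$pwms,
             consensus = pw$consensus, sharedTFs = sharedTFs)
    })
}
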