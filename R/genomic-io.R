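#' Read ChIP-seq peak calls (narrowPeak / broadPeak)
#'
#' Parses MACS2-style peak files into a GRanges with the metadata columns the
#' pipeline consumes: \code{summit} (1-based absolute position), \code{rpmIP},
#' \code{rpmInput}, \code{pvalue} and \code{mark}. narrowPeak files carry the
#' summit offset in column 10; broadPeak files have no summit, so the interval
#' midpoint is used (the only symmetric choice). The p-value column holds
#' -log10(p) in both dialects and is decoded on read.
#'
#' The \code{signalValue} column is interpreted as IP RPM and the
#' \code{qValue} column, when non-negative, as input RPM — the dialect
#' written by \code{\link{writePeaks}}; files from other callers simply get
#' \code{NA} input RPM and are re-quantified from coverage tracks by
#' \code{\link{enrichmentFilter}}.
#'
#' @param path file path.
#' @param mark histone mark label ("H3K4me3" or "H3K27ac").
#' @param format "auto" (by extension), "narrowPeak" or "broadPeak".
#' @return GRanges with summit, rpmIP, rpmInput, pvalue, mark columns.
#' @export
readPeaks <- function(path, mark = NA_character_,
                      format = c("auto", "narrowPeak", "broadPeak")) {
    format <- match.arg(format)
    if (format == "auto") {
        format <- if (grepl("broadPeak$", path)) "broadPeak" else "narrowPeak"
    }
    ncol <- if (format == "narrowPeak") 10L else 9L
    nf <- utils::count.fields(path, sep = "\t", comment.char = "")
    if (length(nf) && any(nf != ncol))
        stopf("malformed %s file '%s': expected %d columns, got %d at line %d",
              format, path, ncol, nf[which(nf != ncol)[1L]],
              which(nf != ncol)[1L])
    extra <- c(signalValue = "numeric", pValue = "numeric",
               qValue = "numeric")
    if (format == "narrowPeak") extra <- c(extra, peak = "integer")
    gr <- rtracklayer::import(path, format = "BED", extraCols = extra)
    if (format == "narrowPeak") {
        # BED start is 0-based; GRanges start is that +1, so the absolute
        # 1-based summit is start(gr) + offset
        summit <- GenomicRanges::start(gr) + gr$peak
        bad <- which(summit < GenomicRanges::start(gr) |
                     summit > GenomicRanges::end(gr))
        if (length(bad))
            stopf("summit outside peak interval at record %d of '%s'",
                  bad[1L], path)
    } else {
        # midpoint of the half-open interval, expressed 1-based
        summit <- (start(gr) - 1L + end(gr)) %/% 2L + 1L
    }
    out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)))
    mcols(out) <- DataFrame(
        name = gr$name,
        summit = as.integer(summit),
        rpmIP = gr$signalValue,
        rpmInput = ifelse(gr$qValue >= 0, gr$qValue, NA_real_),
        pvalue = 10^(-gr$pValue),
        mark = mark)
    out
}

#' Write peaks in narrowPeak or broadPeak dialect
#'
#' Inverse of \code{\link{readPeaks}}: signalValue carries IP RPM, the
#' q-value column carries input RPM (or -1 when unknown) and the p-value
#' column carries -log10(p).
#'
#' @param peaks GRanges as returned by \code{readPeaks}.
#' @param path output path.
#' @param format "narrowPeak" or "broadPeak".
#' @export
writePeaks <- function(peaks, path, format = c("narrowPeak", "broadPeak")) {
    format <- match.arg(format)
    rpmInput <- peaks$rpmInput
    rpmInput[is.na(rpmInput)] <- -1
    fields <- list(
        as.character(seqnames(peaks)),
        start(peaks) - 1L,
        end(peaks),
        if (is.null(peaks$name)) sprintf("peak%d", seq_along(peaks))
        else peaks$name,
        rep(0L, length(peaks)),
        rep(".", length(peaks)),
        fmtNum(peaks$rpmIP, 8),
        fmtNum(-log10(peaks$pvalue), 8),
        fmtNum(rpmInput, 8))
    if (format == "narrowPeak")
        fields <- c(fields, list(peaks$summit - start(peaks)))
    writeLines(do.call(paste, c(fields, sep = "\t")), path)
    invisible(path)
}

#' Read a UCSC chain file
#'
#' Parses the UCSC chain dialect into a \code{\link{ChainSet}}. In the chain
#' header the first (t) side is the source genome of the mapping and the
#' second (q) side the target; the source strand must be '+'. A '-' target
#' strand keeps target coordinates in reverse-complement convention exactly
#' as in the file. Block/gap sums are validated against the declared spans
#' on load and a mismatch is reported with the offending chain id.
#'
#' @param path chain file path.
#' @param sourceSeqinfo,targetSeqinfo optional Seqinfo; reconstructed from
#'   the chain headers when omitted.
#' @return a \code{\link{ChainSet}}.
#' @export
readChain <- function(path, sourceSeqinfo = NULL, targetSeqinfo = NULL) {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines)]
    idx <- grep("^chain\\b", lines)
    if (!length(idx))
        stopf("no chain records found in '%s'", path)
    bounds <- c(idx, length(lines) + 1L)
    recs <- vector("list", length(idx))
    for (i in seq_along(idx)) {
        hdr <- strsplit(trimws(lines[idx[i]]), "\\s+")[[1L]]
        if (length(hdr) != 13L)
            stopf("malformed chain header at line %d of '%s'", idx[i], path)
        body <- lines[(idx[i] + 1L):(bounds[i + 1L] - 1L)]
        body <- body[nzchar(trimws(body))]
        if (!length(body))
            stopf("truncated chain record '%s' in '%s'", hdr[13L], path)
        parts <- strsplit(trimws(body), "\\s+")
        nfield <- lengths(parts)
        if (any(nfield[-length(parts)] != 3L) ||
            nfield[length(parts)] != 1L)
            stopf("truncated or malformed block list for chain '%s'", hdr[13L])
        sz <- as.integer(vapply(parts, `[`, character(1), 1L))
        dt <- as.integer(vapply(parts[-length(parts)], `[`, character(1), 2L))
        dq <- as.integer(vapply(parts[-length(parts)], `[`, character(1), 3L))
        if (hdr[5L] != "+")
            stopf("chain '%s': source strand must be '+'", hdr[13L])
        recs[[i]] <- chainRecord(
            id = hdr[13L], score = as.numeric(hdr[2L]),
            sName = hdr[3L], sSize = as.integer(hdr[4L]),
            sStart = as.integer(hdr[6L]), sEnd = as.integer(hdr[7L]),
            tName = hdr[8L], tSize = as.integer(hdr[9L]),
            tStrand = hdr[10L],
            tStart = as.integer(hdr[11L]), tEnd = as.integer(hdr[12L]),
            size = sz, dt = dt, dq = dq)
        v <- validateChainRecord(recs[[i]])
        if (!isTRUE(v)) stopf("invalid chain in '%s': %s", path, v)
    }
    if (is.null(sourceSeqinfo))
        sourceSeqinfo <- seqinfoFromChains(recs, "s")
    if (is.null(targetSeqinfo))
        targetSeqinfo <- seqinfoFromChains(recs, "t")
    ChainSet(chains = recs, sourceSeqinfo = sourceSeqinfo,
             targetSeqinfo = targetSeqinfo)
}

# assemble a chain record and precompute 0-based block coordinates on both
# sides (target side in the strand convention of the file)
chainRecord <- function(id, score, sName, sSize, sStart, sEnd,
                        tName, tSize, tStrand, tStart, tEnd,
                        size, dt, dq) {
    n <- length(size)
    srcStart <- sStart + c(0L, cumsum(size[-n] + dt))
    tgtStart <- tStart + c(0L, cumsum(size[-n] + dq))
    list(id = id, score = score,
         sName = sName, sSize = sSize, sStart = sStart, sEnd = sEnd,
         tName = tName, tSize = tSize, tStrand = tStrand,
         tStart = tStart, tEnd = tEnd,
         size = size, dt = dt, dq = dq,
         blockSrcStart = srcStart, blockSrcEnd = srcStart + size,
         blockTgtStart = tgtStart, blockTgtEnd = tgtStart + size)
}

seqinfoFromChains <- function(recs, side) {
    nm <- vapply(recs, `[[`, character(1), paste0(side, "Name"))
    sz <- vapply(recs, `[[`, integer(1), paste0(side, "Size"))
    keep <- !duplicated(nm)
    Seqinfo(seqnames = nm[keep], seqlengths = sz[keep])
}

#' Write a ChainSet as a UCSC chain file
#' @param chainSet a \code{\link{ChainSet}}.
#' @param path output path.
#' @export
writeChain <- function(chainSet, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (ch in chains(chainSet)) {
        writeLines(sprintf("chain %s %s %d + %d %d %s %d %s %d %d %s",
                           fmtNum(ch$score, 12), ch$sName, ch$sSize,
                           ch$sStart, ch$sEnd, ch$tName, ch$tSize,
                           ch$tStrand, ch$tStart, ch$tEnd, ch$id), con)
        n <- length(ch$size)
        if (n > 1L)
            writeLines(sprintf("%d\t%d\t%d", ch$size[-n], ch$dt, ch$dq), con)
        writeLines(sprintf("%d", ch$size[n]), con)
        writeLines("", con)
    }
    invisible(path)
}

#' Read transcription start sites from GTF or BED6
#'
#' For + strand features the TSS is the leftmost base; for - strand the
#' rightmost. Strand is required: enhancer classification is undefined
#' without oriented TSS windows. GTF input keeps \code{gene} features (or
#' \code{transcript} when no gene features exist).
#'
#' @param path GTF (.gtf) or BED6 file.
#' @return GRanges of width-1 TSS positions with a \code{gene_id} column.
#' @export
readTSS <- function(path) {
    if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) {
        gr <- rtracklayer::import(path, format = "gtf")
        if (any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
        else if (any(gr$type == "transcript")) gr <- gr[gr$type == "transcript"]
        ids <- gr$gene_id
    } else {
        gr <- rtracklayer::import(path, format = "BED")
        ids <- gr$name
    }
    tssFromGenes(gr, ids)
}

# shared by readTSS and the generator
tssFromGenes <- function(gr, ids) {
    st <- as.character(strand(gr))
    if (any(st == "*" | st == "."))
        stopf("strand is required for TSS derivation (found '.'/'*' at record %d)",
              which(st == "*" | st == ".")[1L])
    pos <- ifelse(st == "+", start(gr), end(gr))
    out <- GRanges(seqnames(gr), IRanges(pos, width = 1L), strand = st)
    out$gene_id <- ids
    seqinfo(out) <- seqinfo(gr)
    out
}

#' Write gene models as GTF
#' @param genes GRanges with gene_id metadata.
#' @param path output path.
#' @export
writeGenesGtf <- function(genes, path) {
    lines <- sprintf(
        '%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
        as.character(seqnames(genes)), start(genes), end(genes),
        as.character(strand(genes)), genes$gene_id)
    writeLines(lines, path)
    invisible(path)
}

#' Read/write coverage tracks (bedGraph with a library-size header)
#'
#' The on-disk form is bedGraph whose track line declares the library size
#' (\code{totalReads=}) and nominal resolution (\code{binSize=}); interval
#' scores are read counts. RPM computation always uses the declared library
#' size, so sparse tracks (zero outside peaks) are well defined.
#'
#' @param track a \code{\link{CoverageTrack}}.
#' @param path file path.
#' @return \code{readCoverageTrack}: a \code{\link{CoverageTrack}}.
#' @export
writeCoverageTrack <- function(track, path) {
    gr <- coverageRanges(track)
    header <- sprintf(
        "track type=bedGraph totalReads=%s binSize=%d",
        fmtNum(totalReads(track), 12), track@binSize)
    body <- sprintf("%s\t%d\t%d\t%s",
                    as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                    fmtNum(gr$score, 10))
    writeLines(c(header, body), path)
    invisible(path)
}

#' @rdname writeCoverageTrack
#' @export
readCoverageTrack <- function(path) {
    first <- readLines(path, n = 1L)
    m <- regmatches(first, regexec("totalReads=([0-9eE.+-]+)", first))[[1L]]
    if (length(m) < 2L)
        stopf("coverage track '%s' lacks a totalReads= header", path)
    total <- as.numeric(m[2L])
    b <- regmatches(first, regexec("binSize=([0-9]+)", first))[[1L]]
    binSize <- if (length(b) >= 2L) as.integer(b[2L]) else 10L
    gr <- rtracklayer::import(path, format = "bedGraph")
    CoverageTrack(cov = gr, totalReads = total, binSize = binSize)
}

#' Read/write chromosome sizes
#' @param path two-column TSV (name, length), no header.
#' @return \code{readChromSizes}: a Seqinfo.
#' @export
readChromSizes <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("chrom", "len"),
                            stringsAsFactors = FALSE)
    Seqinfo(seqnames = df$chrom, seqlengths = df$len)
}

#' @rdname readChromSizes
#' @param si a Seqinfo.
#' @export
writeChromSizes <- function(si, path) {
    writeLines(sprintf("%s\t%d", GenomeInfoDb::seqnames(si),
                       seqlengths(si)), path)
    invisible(path)
}

#' Read/write position weight matrices (MEME-minimal text)
#'
#' Matrices are stored as position-by-base probability rows (A C G T). On
#' read, each row is renormalized with the declared pseudocount so rows sum
#' to one; a position whose probabilities are all zero is rejected.
#'
#' @param path MEME-minimal text file.
#' @param pseudocount added to every probability before renormalization.
#' @return \code{readPWMSet}: named list of w-by-4 probability matrices
#'   (columns A, C, G, T), with a \code{background} attribute.
#' @export
readPWMSet <- function(path, pseudocount = 0.001) {
    lines <- readLines(path)
    bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
    bgLine <- grep("^Background letter frequencies", lines)
    if (length(bgLine)) {
        tok <- strsplit(trimws(lines[bgLine[1L] + 1L]), "\\s+")[[1L]]
        bg <- stats::setNames(as.numeric(tok[c(2, 4, 6, 8)]),
                              tok[c(1, 3, 5, 7)])[c("A", "C", "G", "T")]
    }
    starts <- grep("^MOTIF\\b", lines)
    pwms <- list()
    bounds <- c(starts, length(lines) + 1L)
    for (i in seq_along(starts)) {
        name <- strsplit(trimws(lines[starts[i]]), "\\s+")[[1L]][2L]
        blk <- lines[(starts[i] + 1L):(bounds[i + 1L] - 1L)]
        hdr <- grep("letter-probability matrix", blk)
        if (!length(hdr)) stopf("motif '%s': missing probability matrix", name)
        w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", blk[hdr[1L]]))
        rows <- blk[(hdr[1L] + 1L):(hdr[1L] + w)]
        mat <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"),
                                     as.numeric))
        colnames(mat) <- c("A", "C", "G", "T")
        # pseudocount only where needed: matrices already carrying mass on
        # every base are just renormalized, so write/read round-trips
        pwms[[name]] <- normalizePWM(mat,
                                     if (any(mat == 0)) pseudocount else 0)
    }
    attr(pwms, "background") <- bg
    pwms
}

#' @rdname readPWMSet
#' @param pwms named list of probability matrices.
#' @export
writePWMSet <- function(pwms, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
                 "Background letter frequencies",
                 "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
    for (nm in names(pwms)) {
        m <- pwms[[nm]]
        writeLines(sprintf("MOTIF %s", nm), con)
        writeLines(sprintf(
            "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
            nrow(m)), con)
        writeLines(apply(m, 1L, function(r)
            paste(sprintf("%.6f", r), collapse = " ")), con)
        writeLines("", con)
    }
    invisible(path)
}

# renormalize a PWM row-wise with a pseudocount; reject degenerate rows
normalizePWM <- function(mat, pseudocount = 0.001) {
    if (ncol(mat) != 4L) stopf("PWM must have 4 base columns")
    if (any(rowSums(mat) == 0))
        stopf("degenerate PWM: position %d has all-zero probabilities",
              which(rowSums(mat) == 0)[1L])
    out <- (mat + pseudocount) / (rowSums(mat) + 4 * pseudocount)
    colnames(out) <- c("A", "C", "G", "T")
    out
}

#' Read/write chromatin-state segmentations
#'
#' BED-like TSV with columns chrom, start (0-based), end, state, tissue.
#' Segments within a tissue must be non-overlapping.
#'
#' @param path file path.
#' @return \code{readStateSegments}: GRanges with \code{state} and
#'   \code{tissue} columns.
#' @export
readStateSegments <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("chrom", "start", "end",
                                          "state", "tissue"),
                            stringsAsFactors = FALSE)
    gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
    gr$state <- df$state
    gr$tissue <- df$tissue
    for (ti in unique(gr$tissue)) {
        sub <- gr[gr$tissue == ti]
        if (length(sub) > 1L &&
            any(countOverlaps(sub, sub, type = "any") > 1L))
            stopf("state segments overlap within tissue '%s'", ti)
    }
    gr
}

#' @rdname readStateSegments
#' @param segments GRanges with state and tissue columns.
#' @export
writeStateSegments <- function(segments, path) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s",
                       as.character(seqnames(segments)),
                       start(segments) - 1L, end(segments),
                       segments$state, segments$tissue), path)
    invisible(path)
}

#' Read/write expression matrices (TSV, genes x samples)
#' @param path file path.
#' @return \code{readExpression}: numeric matrix with gene-id rownames.
#' @export
readExpression <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            row.names = 1L, check.names = FALSE)
    as.matrix(df)
}

#' @rdname readExpression
#' @param mat numeric matrix with gene-id rownames.
#' @export
writeExpression <- function(mat, path) {
    df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
    writeTsv(df, path)
}

#' Read a one-to-one orthology table
#'
#' TSV with columns gene_source, gene_target, homology_type; only rows
#' whose type is "one2one" are returned.
#'
#' @param path file path.
#' @return data.frame with gene_source and gene_target columns.
#' @export
readOrthology <- function(path) {
    df <- readTsv(path)
    df[df$homology_type == "one2one",
       c("gene_source", "gene_target"), drop = FALSE]
}

#' Write classified elements as BED6+ with class and summit columns
#' @param elements GRanges with elementClass (and optionally summit, rpmIP).
#' @param path output path.
#' @export
writeElementsBed <- function(elements, path) {
    score <- if (is.null(elements$rpmIP)) rep(0, length(elements))
             else elements$rpmIP
    summit <- if (is.null(elements$summit)) rep(-1L, length(elements))
              else elements$summit - 1L
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t.\t%s\t%d",
                       as.character(seqnames(elements)),
                       start(elements) - 1L, end(elements),
                       if (is.null(elements$name))
                           sprintf("el%d", seq_along(elements))
                       else elements$name,
                       fmtNum(score, 8),
                       elements$elementClass, summit), path)
    invisible(path)
}
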