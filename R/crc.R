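#' Scan a sequence with a position weight matrix
#'
#' Log-odds scan in bits: at each position the score is the sum over motif
#' columns of log2(p_base / q_base) against the background; N bases
#' contribute 0 (scored as background). Both strands are scanned — the
#' reverse strand by scoring the reverse-complemented PWM on the forward
#' sequence — and positions with score >= threshold are reported as hits.
#'
#' @param sequence character string or DNAString over A/C/G/T/N.
#' @param pwm w-by-4 probability matrix (columns A, C, G, T), already
#'   pseudocount-normalized (see \code{\link{readPWMSet}}).
#' @param background base frequencies (A, C, G, T).
#' @param threshold minimum score in bits (default 6).
#' @return data.frame with \code{pos} (1-based start on the forward
#'   sequence), \code{strand} and \code{score} for each hit.
#' @export
scanPWM <- function(sequence, pwm, background = rep(0.25, 4),
                    threshold = 6) {
    seqc <- toupper(as.character(sequence))
    L <- nchar(seqc)
    w <- nrow(pwm)
    empty <- data.frame(pos = integer(), strand = character(),
                        score = numeric(), stringsAsFactors = FALSE)
    if (L < w) return(empty)
    code <- match(strsplit(seqc, "")[[1L]], c("A", "C", "G", "T"))
    code[is.na(code)] <- 5L  # N and anything else: background
    scoreStrand <- function(mat) {
        lo <- log2(sweep(mat, 2L, background, "/"))
        lut <- rbind(t(lo), 0)          # 5 x w; row 5 = N -> 0
        ns <- L - w + 1L
        sc <- numeric(ns)
        for (j in seq_len(w))
            sc <- sc + lut[cbind(code[j:(j + ns - 1L)], j)]
        sc
    }
    fwd <- scoreStrand(pwm)
    rvs <- scoreStrand(reverseComplementPWM(pwm))
    strandHits <- function(sc, st) {
        i <- which(sc >= threshold)
        data.frame(pos = i, strand = rep(st, length(i)), score = sc[i],
                   stringsAsFactors = FALSE)
    }
    hits <- rbind(strandHits(fwd, "+"), strandHits(rvs, "-"))
    hits[order(hits$pos, hits$strand), , drop = FALSE]
}

#' Reverse-complement a PWM
#' @param pwm w-by-4 probability matrix (columns A, C, G, T).
#' @return the PWM of the reverse-complement motif.
#' @export
reverseComplementPWM <- function(pwm) {
    out <- pwm[rev(seq_len(nrow(pwm))), c("T", "G", "C", "A"), drop = FALSE]
    colnames(out) <- c("A", "C", "G", "T")
    out
}

#' Candidate core transcription factors
#'
#' A TF is a CRC candidate when a super-enhancer is assigned to its gene
#' and it is expressed at or above \code{minTpm}.
#'
#' @param seGenes character vector of genes with an assigned super-enhancer.
#' @param tfList character vector of TF gene names (non-empty).
#' @param tpm named numeric vector of expression values.
#' @param minTpm expression floor (default 1 TPM).
#' @return character vector of candidate TF names.
#' @export
candidateTFs <- function(seGenes, tfList, tpm, minTpm = 1) {
    if (!length(tfList)) stopf("empty TF list")
    cand <- intersect(tfList, seGenes)
    cand[!is.na(tpm[cand]) & tpm[cand] >= minTpm]
}

#' Build the core regulatory circuitry graph
#'
#' A candidate TF becomes a node iff its own motif hits its own
#' super-enhancer constituent sequences (auto-regulation). A directed edge
#' A -> B is drawn when A's motif hits B's constituents. Core circuitries
#' are the maximal cliques of the mutual (bidirectional) graph, enumerated
#' exactly (Bron-Kerbosch via igraph); graphs beyond 64 nodes are refused.
#'
#' @param candidates character vector of candidate TF names.
#' @param constituentSeqs named list (per TF) of character vectors of
#'   constituent sequences; candidates without sequences are dropped with a
#'   warning.
#' @param pwms named list of PWMs (see \code{\link{readPWMSet}}); candidates
#'   without a PWM are dropped with a warning.
#' @param threshold log-odds bit threshold for \code{\link{scanPWM}}.
#' @param background base frequencies.
#' @return list: \code{nodes} (auto-regulated TFs), \code{adjacency}
#'   (logical matrix over nodes, A row -> B column), \code{cliques} (list of
#'   character vectors, maximal mutual cliques), \code{edges} (data.frame
#'   from, to).
#' @export
buildCRC <- function(candidates, constituentSeqs, pwms, threshold = 6,
                     background = rep(0.25, 4)) {
    drop <- candidates[!candidates %in% names(pwms)]
    if (length(drop))
        warnf("candidate(s) without a PWM excluded: %s",
              paste(drop, collapse = ", "))
    candidates <- setdiff(candidates, drop)
    drop2 <- candidates[!candidates %in% names(constituentSeqs)]
    if (length(drop2))
        warnf("candidate(s) without constituent sequences excluded: %s",
              paste(drop2, collapse = ", "))
    candidates <- setdiff(candidates, drop2)
    if (length(candidates) > 64L)
        stopf("CRC graph capped at 64 nodes (got %d)", length(candidates))
    if (!length(candidates))
        return(list(nodes = character(), adjacency = matrix(FALSE, 0, 0),
                    cliques = list(),
                    edges = data.frame(from = character(),
                                       to = character())))
    hitsIn <- function(tf, targetSeqs) {
        any(vapply(targetSeqs, function(s)
            nrow(scanPWM(s, pwms[[tf]], background, threshold)) > 0L,
            logical(1)))
    }
    nodes <- candidates[vapply(candidates, function(tf)
        hitsIn(tf, constituentSeqs[[tf]]), logical(1))]
    n <- length(nodes)
    adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
    for (a in nodes) for (b in nodes)
        adj[a, b] <- hitsIn(a, constituentSeqs[[b]])
    cliques <- enumerateMutualCliques(adj)
    ed <- which(adj, arr.ind = TRUE)
    list(nodes = nodes, adjacency = adj, cliques = cliques,
         edges = data.frame(from = nodes[ed[, 1L]], to = nodes[ed[, 2L]],
                            stringsAsFactors = FALSE))
}

# maximal cliques of the mutual (A->B and B->A) graph
enumerateMutualCliques <- function(adj) {
    n <- nrow(adj)
    if (n == 0L) return(list())
    mutual <- adj & t(adj)
    diag(mutual) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(mutual, mode = "undirected")
    cl <- igraph::max_cliques(g)
    out <- lapply(cl, function(v) sort(names(v)))
    out[order(-lengths(out),
              vapply(out, paste, character(1), collapse = ","))]
}

#' Compare core regulatory circuitries across species
#'
#' Intersects clique-member TF name sets across species (case-insensitive,
#' on orthologous names) and reports per-species specific sets, plus the
#' fraction of the union shared by all species and the fractions shared by
#' at least two.
#'
#' @param crcs named list (per species) of \code{\link{buildCRC}} results,
#'   at least two.
#' @return list: \code{shared} (TFs in every species), \code{specific}
#'   (per-species TFs found nowhere else), \code{sets} (the per-species
#'   member sets), \code{nShared}, \code{fracSharedAll} (shared / union),
#'   \code{fracSharedAtLeast2}.
#' @export
compareCRCs <- function(crcs) {
    if (length(crcs) < 2L) stopf("need CRCs from at least 2 species")
    sets <- lapply(crcs, function(cc)
        sort(unique(toupper(unlist(cc$cliques)))))
    shared <- Reduce(intersect, sets)
    uni <- sort(unique(unlist(sets)))
    cnt <- table(unlist(lapply(sets, unique)))
    specific <- lapply(names(sets), function(sp)
        setdiff(sets[[sp]], unlist(sets[setdiff(names(sets), sp)])))
    names(specific) <- names(sets)
    list(shared = shared, specific = specific, sets = sets,
         nShared = length(shared),
         fracSharedAll = if (length(uni)) length(shared) / length(uni)
                         else NA_real_,
         fracSharedAtLeast2 = if (length(uni))
             sum(cnt >= 2L) / length(uni) else NA_real_)
}
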