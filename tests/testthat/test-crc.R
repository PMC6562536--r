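# PWM scanning and core-regulatory-circuitry construction.

test_that("log-odds scan scores planted consensus and uniform PWMs", {
    pw <- CREconserve:::normalizePWM(
        matrix(c(1, 0, 0, 0,   # A
                 0, 1, 0, 0,   # C
                 0, 0, 1, 0,   # G
                 0, 0, 1, 0),  # G  (non-palindromic ACGG)
               4L, 4L, byrow = TRUE))
    hits <- scanPWM("ACGG", pw, threshold = 6)
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$strand, "+")
    # hand computation: 4 * log2(((1 + 0.001) / 1.004) / 0.25)
    expect_equal(hits$score, 4 * log2((1.001 / 1.004) / 0.25),
                 tolerance = 1e-9)
    expect_equal(hits$score, 7.98, tolerance = 0.01)
    # uniform PWM scores 0 everywhere: no hits above a positive threshold
    uni <- matrix(0.25, 6L, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
    expect_equal(nrow(scanPWM("ACGTACGTACGT", uni, threshold = 0.5)), 0L)
    all0 <- scanPWM("ACGTACGTACGT", uni, threshold = -1)
    expect_true(all(abs(all0$score) < 1e-12))
    # shorter than the motif: zero hits; N scores as background
    expect_equal(nrow(scanPWM("AC", pw, threshold = -100)), 0L)
    hN <- scanPWM("ANGG", pw, threshold = 0)
    expect_equal(hN$score[hN$strand == "+"],
                 3 * log2((1.001 / 1.004) / 0.25), tolerance = 1e-9)
})

test_that("planted occurrences are recovered and strands are symmetric", {
    pwset <- generatePWMSet("TFX", seed = 2L, width = 8L)
    cons <- pwset$consensus[["TFX"]]
    set.seed(77)
    s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    s <- plantMotif(s, cons, c(11, 101, 201))
    hits <- scanPWM(s, pwset$pwms$TFX, threshold = 6)
    expect_gte(nrow(hits), 3L)
    expect_true(all(c(11, 101, 201) %in% hits$pos))
    # scanning the reverse complement finds the same score multiset
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    hitsRc <- scanPWM(rc, pwset$pwms$TFX, threshold = 6)
    expect_equal(sort(hitsRc$score), sort(hits$score), tolerance = 1e-9)
    # per-position oracle: independent sum of per-column log-odds
    lo <- log2(pwset$pwms$TFX / 0.25)
    ch <- strsplit(s, "")[[1L]]
    fwd <- hits[hits$strand == "+", ]
    for (r in seq_len(nrow(fwd))) {
        p <- fwd$pos[r]
        sc <- sum(vapply(1:8, function(j)
            lo[j, ch[p + j - 1L]], numeric(1)))
        expect_equal(fwd$score[r], sc, tolerance = 1e-9)
    }
})

test_that("candidate TFs need a super-enhancer and expression", {
    tpm <- c(TF1 = 10, TF2 = 0, TF3 = 5)
    expect_equal(candidateTFs(c("TF1", "TF2", "gX"),
                              c("TF1", "TF2", "TF3"), tpm), "TF1")
    expect_error(candidateTFs("TF1", character(), tpm), "TF list")
})

test_that("CRC graph: auto-regulation, directionality and cliques", {
    pwset <- generatePWMSet(c("A1", "B1", "C1"), seed = 4L)
    cons <- pwset$consensus
    rseq <- function() paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                             collapse = "")
    set.seed(55)
    # complete graph: every motif planted in every constituent
    seqsAll <- lapply(c("A1", "B1", "C1"), function(tf) {
        s <- rseq()
        for (j in seq_along(cons)) s <- plantMotif(s, cons[[j]], 30 * j)
        s
    })
    names(seqsAll) <- c("A1", "B1", "C1")
    crc <- buildCRC(c("A1", "B1", "C1"), seqsAll, pwset$pwms)
    expect_setequal(crc$nodes, c("A1", "B1", "C1"))
    expect_equal(crc$cliques[[1L]], c("A1", "B1", "C1"))
    # chain A -> B -> C without reciprocation: largest clique is a singleton
    seqsChain <- list(
        A1 = plantMotif(rseq(), cons[["A1"]], 10),             # self only
        B1 = plantMotif(plantMotif(rseq(), cons[["B1"]], 10),
                        cons[["A1"]], 40),
        C1 = plantMotif(plantMotif(rseq(), cons[["C1"]], 10),
                        cons[["B1"]], 40))
    crc2 <- buildCRC(c("A1", "B1", "C1"), seqsChain, pwset$pwms)
    expect_equal(max(lengths(crc2$cliques)), 1L)
    # candidates without a PWM are dropped with a warning
    expect_warning(
        crc3 <- buildCRC(c("A1", "ZZ"), seqsAll["A1"], pwset$pwms["A1"]),
        "ZZ")
    expect_equal(crc3$nodes, "A1")
})

test_that("clique enumeration equals the exhaustive subset scan", {
    set.seed(66)
    for (rep in 1:5) {
        n <- sample(5:10, 1)
        adj <- matrix(runif(n * n) < 0.5, n, n,
                      dimnames = list(sprintf("t%02d", 1:n),
                                      sprintf("t%02d", 1:n)))
        diag(adj) <- TRUE
        got <- CREconserve:::enumerateMutualCliques(adj)
        expect_identical(got, oracleCliques(adj))
    }
})

test_that("cross-species CRC comparison recovers planted overlap", {
    a <- list(cliques = list(c("X", "Y", "Z")))
    expect_equal(compareCRCs(list(s1 = a, s2 = a))$shared,
                 c("X", "Y", "Z"))
    b <- list(cliques = list(c("Q", "R")))
    expect_length(compareCRCs(list(s1 = a, s2 = b))$shared, 0L)
    scen <- generateCrcScenario(seed = 9L, nShared = 4L,
                                nSpecific = c(3L, 2L, 2L))
    crcs <- lapply(scen$species, function(sp)
        buildCRC(sp$candidates, sp$constituentSeqs, scen$pwms))
    cmp <- compareCRCs(crcs)
    expect_setequal(cmp$shared, scen$sharedTFs)
})
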