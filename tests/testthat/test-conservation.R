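# Chain mapping with minimum-match semantics, conservation classification,
# distance distributions and the chromatin-state overlay.

test_that("identity chains map intervals onto themselves", {
    si <- tinySeqinfo()
    cs <- identityChainSet(si, targetPrefix = "t_")
    gr <- GRanges(c("chr1", "chr2"), IRanges(c(101, 5001), c(2100, 7000)))
    mp <- mapIntervals(gr, cs)
    expect_true(all(mp$mapped))
    expect_equal(mp$tStart, start(gr))
    expect_equal(mp$tEnd, end(gr))
    expect_equal(mp$tName, c("t_chr1", "t_chr2"))
    expect_equal(mp$matchFrac, c(1, 1))
})

test_that("minimum match is a hard threshold on aligned bases", {
    # one aligned block chr1:[10000,10500) -> t:[2000,2500); a 2000 bp
    # element with exactly 500 bases inside maps at minMatch 0.2 (0.25)
    # but not at 0.3
    cs <- makeChainSet(
        list(id = "1", score = 1, sName = "chr1", sSize = 100000L,
             sStart = 10000L, sEnd = 10500L, tName = "tchrA",
             tSize = 50000L, tStrand = "+", tStart = 2000L, tEnd = 2500L,
             size = 500L, dt = integer(), dq = integer()),
        sourceLens = c(chr1 = 100000L), targetLens = c(tchrA = 50000L))
    el <- GRanges("chr1", IRanges(10001, 12000))  # 0-based [10000,12000)
    m1 <- mapIntervals(el, cs, LiftOverConfig(minMatch = 0.2))
    expect_true(m1$mapped)
    expect_equal(m1$matchFrac, 0.25)
    expect_equal(c(m1$tStart, m1$tEnd), c(2001L, 2500L))
    m2 <- mapIntervals(el, cs, LiftOverConfig(minMatch = 0.3))
    expect_false(m2$mapped)
    expect_equal(m2$reason, "below_min_match")
})

test_that("reverse-strand chains reflect coordinates as the oracle does", {
    cs <- makeChainSet(
        list(id = "1", score = 1, sName = "chr1", sSize = 10000L,
             sStart = 1000L, sEnd = 4000L, tName = "tchrA", tSize = 8000L,
             tStrand = "-", tStart = 500L, tEnd = 3500L,
             size = 3000L, dt = integer(), dq = integer()),
        sourceLens = c(chr1 = 10000L), targetLens = c(tchrA = 8000L))
    el <- GRanges("chr1", IRanges(1501, 2000))  # fully inside the block
    mp <- mapIntervals(el, cs)
    orc <- oracleMapInterval(cs, "chr1", 1500L, 2000L)
    expect_true(mp$mapped)
    expect_equal(mp$tStrand, "-")
    expect_equal(mp$tEnd - mp$tStart, 499L)  # width preserved
    expect_equal(mp$tStart, orc$tStart)
    expect_equal(mp$tEnd, orc$tEnd)
})

test_that("splits across chains are rejected by default", {
    cs <- makeChainSet(
        list(id = "1", score = 1, sName = "chr1", sSize = 10000L,
             sStart = 0L, sEnd = 2000L, tName = "tchrA", tSize = 9000L,
             tStrand = "+", tStart = 0L, tEnd = 2000L,
             size = 2000L, dt = integer(), dq = integer()),
        list(id = "2", score = 1, sName = "chr1", sSize = 10000L,
             sStart = 2000L, sEnd = 4000L, tName = "tchrB", tSize = 7000L,
             tStrand = "+", tStart = 100L, tEnd = 2100L,
             size = 2000L, dt = integer(), dq = integer()),
        sourceLens = c(chr1 = 10000L),
        targetLens = c(tchrA = 9000L, tchrB = 7000L))
    mp <- mapIntervals(GRanges("chr1", IRanges(1501, 2500)), cs)
    expect_false(mp$mapped)
    expect_equal(mp$reason, "split_across_chains")
    mp2 <- mapIntervals(GRanges("chr1", IRanges(1501, 2500)), cs,
                        LiftOverConfig(allowMultiple = TRUE))
    expect_true(mp2$mapped)
})

test_that("mapping agrees with the per-base oracle on gapped and reverse chains", {
    cfg <- SyntheticConfig(seed = 13L)
    ref <- generateReference(cfg, withSequence = FALSE)
    pair <- generateChainPair(cfg, ref)
    set.seed(99)
    n <- 60
    chrom <- sample(seqnames(ref$seqinfo), n, replace = TRUE)
    s0 <- unname(vapply(chrom, function(cc)
        sample.int(seqlengths(ref$seqinfo)[[cc]] - 3000L, 1L), integer(1)))
    w <- sample(50:600, n, replace = TRUE)
    gr <- GRanges(chrom, IRanges(s0 + 1L, s0 + w))
    mp <- mapIntervals(gr, pair$chainSet)
    for (i in seq_len(n)) {
        orc <- oracleMapInterval(pair$chainSet, as.character(chrom[i]),
                                 s0[i], s0[i] + w[i])
        expect_equal(mp$mapped[i], orc$mapped)
        if (orc$mapped) {
            expect_equal(mp$tStart[i], orc$tStart)
            expect_equal(mp$tEnd[i], orc$tEnd)
            expect_equal(mp$matchFrac[i], orc$matchFrac, tolerance = 1e-12)
        } else {
            expect_equal(mp$reason[i], orc$reason)
        }
    }
})

test_that("conservation classification is class-matched and partitions", {
    si <- tinySeqinfo()
    cs <- identityChainSet(si, "t_")
    el <- makePeaks("chr1", c(1001, 5001, 9001), c(3000, 7000, 11000))
    el$elementClass <- "enhancer"
    tgt <- GRanges("t_chr1", IRanges(c(3000, 5500), c(3600, 6500)))
    tgt$elementClass <- c("enhancer", "active_promoter")
    tgt$name <- c("tA", "tB")
    cons <- classifyConservation(el, cs, tgt)
    # 1 bp overlap with a same-class target -> functional
    expect_equal(cons$status,
                 c("functional", "sequence_only", "sequence_only"))
    expect_equal(cons$matchedTarget[1L], "tA")
    # the three statuses partition the element set
    expect_equal(sum(cons$status == "functional") +
                 sum(cons$status == "sequence_only") +
                 sum(cons$status == "un_conserved"), nrow(cons))
    # class missing from the target set -> warning, sequence_only
    el2 <- el[1]; el2$elementClass <- "broad_domain"
    expect_warning(c2 <- classifyConservation(el2, cs, tgt), "absent")
    expect_equal(c2$status, "sequence_only")
})

test_that("planted conservation fractions are recovered on a synthetic pair", {
    cfg <- SyntheticConfig(seed = 23L, fracFunctional = 0.3,
                           fracSequenceOnly = 0.55)
    ref <- generateReference(cfg, withSequence = FALSE)
    pc <- generatePeaksAndCoverage(cfg, ref, withCoverage = FALSE)
    enh <- classifyElements(
        filterPeaksByPvalue(pc$h3k4me3, "narrow"),
        filterPeaksByPvalue(pc$h3k27ac, "narrow"), ref$tss)
    enh <- enh[enh$elementClass == "enhancer"]
    std <- standardizeElements(enh, ref$seqinfo)
    pair <- generateChainPair(cfg, ref, elements = std)
    cons <- classifyConservation(std, pair$chainSet, pair$targetElements)
    expect_identical(cons$status, unname(pair$plantedStatus))
    n <- nrow(cons)
    expect_equal(sum(cons$status == "functional") / n, 0.30,
                 tolerance = 0.02)
    expect_equal(sum(cons$status == "sequence_only") / n, 0.55,
                 tolerance = 0.02)
})

test_that("distance to the nearest gene matches the exhaustive scan", {
    tss <- makeTss("chr1", c(10001, 50001), "+")
    onTss <- GRanges("chr1", IRanges(9001, 11000))  # midpoint 10000/10001
    expect_lte(distanceToNearestGene(onTss, tss), 1L)
    far <- GRanges("chr1", IRanges(15001, 15001))
    expect_equal(distanceToNearestGene(far, tss), 5000L)
    set.seed(3)
    tssR <- makeTss("chr1", sort(sample(1000:99000, 30)), "+")
    elR <- GRanges("chr1", IRanges(s <- sample(1:99000, 50), s + 500))
    got <- distanceToNearestGene(elR, tssR)
    mid <- floor((start(elR) + end(elR)) / 2)
    want <- vapply(mid, function(m) min(abs(m - start(tssR))), numeric(1))
    expect_equal(got, as.integer(want))
})

test_that("KS comparison and its random control behave", {
    set.seed(6)
    a <- rnorm(500); b <- rnorm(500)
    same <- ksCompareWithRandomControl(a, a, c(a, b), nDraws = 3L,
                                       drawSize = 100L, seed = 1L)
    expect_equal(same$statistic, 0)
    expect_equal(same$p.value, 1)
    shifted <- ksCompareWithRandomControl(a, b + 1, c(a, b), nDraws = 3L,
                                          drawSize = 100L, seed = 1L)
    # D equals the brute-force sup-difference of the two ECDFs
    grid <- sort(c(a, b + 1))
    D <- max(abs(ecdf(a)(grid) - ecdf(b + 1)(grid)))
    expect_equal(shifted$statistic, D, tolerance = 1e-12)
    again <- ksCompareWithRandomControl(a, b + 1, c(a, b), nDraws = 3L,
                                        drawSize = 100L, seed = 1L)
    expect_identical(shifted$controls, again$controls)
    expect_error(
        ksCompareWithRandomControl(a, b, a, drawSize = 1000L, seed = 1L),
        "pool")
})

test_that("state overlay picks the largest-overlap state per tissue", {
    si <- Seqinfo("t_chr1", 100000L)
    el <- GRanges("t_chr1", IRanges(c(1001, 5001, 9001),
                                    c(2000, 6000, 10000)))
    seg <- GRanges("t_chr1",
                   IRanges(c(1, 1001, 5001, 5601, 9001),
                           c(1000, 5000, 5600, 9000, 100000)))
    seg$state <- c("Quies", "EnhA1", "EnhA1", "Quies", "Quies")
    seg$tissue <- "kidney"
    ov <- overlayChromatinStates(el, seg, defaultStateCategoryMap())
    # element 1 fully inside EnhA1; element 2 split 60/40 towards EnhA1;
    # element 3 only quiescent
    expect_equal(unname(ov$matrix[, "kidney"]),
                 c("active_enhancer", "active_enhancer", "other"))
    expect_equal(ov$nRegulatoryAny, 2L)
    expect_equal(unname(ov$perTissue["kidney"]), 2)
})

test_that("state-matrix k-means recovers planted blobs and is seeded", {
    mat <- rbind(
        matrix("active_enhancer", 30, 4),
        matrix("other", 30, 4))
    colnames(mat) <- paste0("t", 1:4)
    cl <- clusterStateMatrix(mat, k = 2L, seed = 42L)
    expect_length(unique(cl[1:30]), 1L)
    expect_length(unique(cl[31:60]), 1L)
    expect_true(cl[1] != cl[31])
    expect_identical(cl, clusterStateMatrix(mat, k = 2L, seed = 42L))
    # k equal to the number of distinct rows: singleton clusters
    m2 <- matrix(c("a", "b", "c", "d"), 4, 1)
    expect_length(unique(clusterStateMatrix(m2, k = 4L, seed = 1L)), 4L)
    expect_error(clusterStateMatrix(m2, k = 5L, seed = 1L), "exceeds")
})
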