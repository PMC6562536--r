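# Generator contracts: determinism, planted structure, sizing errors.

test_that("reference generation is deterministic and respects bounds", {
    cfg <- SyntheticConfig(seed = 1L, nChroms = 2L, chromLen = 1000000L,
                           nGenes = 50L)
    r1 <- generateReference(cfg)
    r2 <- generateReference(cfg)
    expect_identical(as.character(r1$genome), as.character(r2$genome))
    expect_identical(start(r1$genes), start(r2$genes))
    expect_identical(r1$expression, r2$expression)
    # 50 TSS records, all within chromosome bounds, strand-consistent
    expect_length(r1$tss, 50L)
    expect_true(all(start(r1$tss) >= 1L &
                    start(r1$tss) <= seqlengths(r1$seqinfo)[
                        as.character(seqnames(r1$tss))]))
    plus <- as.character(strand(r1$genes)) == "+"
    expect_equal(start(r1$tss)[plus], start(r1$genes)[plus])
    expect_equal(start(r1$tss)[!plus], end(r1$genes)[!plus])
    # genes never overlap
    expect_true(all(countOverlaps(r1$genes, r1$genes) == 1L))
    expect_true(all(r1$expression >= 0))
})

test_that("empty and undersized configurations are handled", {
    r0 <- generateReference(SyntheticConfig(seed = 1L, nGenes = 0L),
                            withSequence = FALSE)
    expect_length(r0$genes, 0L)
    expect_equal(nrow(r0$expression), 0L)
    expect_error(
        generateReference(SyntheticConfig(seed = 1L, chromLen = 50000L,
                                          nGenes = 100L, nChroms = 1L)),
        "too short")
    expect_error(SyntheticConfig(fracFunctional = 0.7,
                                 fracSequenceOnly = 0.6), "<= 1")
})

test_that("peak generator plants TSS structure and exact zero-noise RPM", {
    cfg <- SyntheticConfig(seed = 2L, noiseSd = 0, fracK4AtTss = 1.0)
    ref <- generateReference(cfg, withSequence = FALSE)
    pc <- generatePeaksAndCoverage(cfg, ref)
    win <- tssWindows(ref$tss)
    # every H3K4me3 peak placed inside a TSS window: none enhancer-like
    expect_equal(sum(countOverlaps(pc$h3k4me3, win) == 0L), 0L)
    # distal H3K27ac fraction as configured
    distal <- countOverlaps(pc$h3k27ac, win) == 0L &
        countOverlaps(pc$h3k27ac, pc$h3k4me3) == 0L
    expect_equal(mean(distal), cfg@fracK27Distal, tolerance = 0.01)
    # zero coverage noise: recomputed RPM equals the record exactly
    rpm4 <- rpmInRegion(pc$ipK4, pc$h3k4me3)
    expect_equal(rpm4, pc$h3k4me3$rpmIP, tolerance = 1e-9)
    rpm27 <- rpmInRegion(pc$ipK27, pc$h3k27ac)
    expect_equal(rpm27, pc$h3k27ac$rpmIP, tolerance = 1e-9)
})

test_that("enhancer signal is heavy-tailed enough for an elbow", {
    cfg <- SyntheticConfig(seed = 3L, seTailExponent = 1.5)
    ref <- generateReference(cfg, withSequence = FALSE)
    pc <- generatePeaksAndCoverage(cfg, ref, withCoverage = FALSE)
    sig <- pc$h3k27ac$rpmIP[pc$h3k27ac$kind == "distal"]
    expect_gte(max(sig), 10 * median(sig))
})

test_that("chain pair: identity case, reverse reflection and round-trip", {
    cfg <- SyntheticConfig(seed = 4L)
    ref <- generateReference(cfg, withSequence = FALSE)
    # full-coverage no-indel chain maps everything onto itself
    idcs <- identityChainSet(ref$seqinfo)
    el <- GRanges("chr1", IRanges(c(5001, 70001), c(7000, 72000)))
    mp <- mapIntervals(el, idcs)
    expect_equal(mp$tStart, start(el))
    expect_equal(mp$tEnd, end(el))

    pair <- generateChainPair(cfg, ref)
    chs <- chains(pair$chainSet)
    expect_true(any(vapply(chs, function(ch) ch$tStrand == "-",
                           logical(1))))
    expect_true(any(vapply(chs, function(ch) any(ch$dt > 0 & ch$dq == 0),
                           logical(1))))  # deletions
    expect_true(any(vapply(chs, function(ch) any(ch$dq > 0 & ch$dt == 0),
                           logical(1))))  # insertions
    # chain file round-trip preserves the block structure
    f <- withr::local_tempfile(fileext = ".chain")
    writeChain(pair$chainSet, f)
    back <- readChain(f)
    for (i in seq_along(chs)) {
        expect_equal(chains(back)[[i]]$size, chs[[i]]$size)
        expect_equal(chains(back)[[i]]$dt, chs[[i]]$dt)
        expect_equal(chains(back)[[i]]$dq, chs[[i]]$dq)
        expect_equal(chains(back)[[i]]$tStrand, chs[[i]]$tStrand)
    }
    # planted functional elements on the reverse-strand chromosome map to
    # the planted target elements (reflection handled consistently)
    revChrom <- chs[[length(chs)]]$sName
    onRev <- which(as.character(seqnames(ref$tss)) == revChrom &
                   pair$plantedStatus == "functional")
    expect_gt(length(onRev), 0L)
    sl <- seqlengths(ref$seqinfo)[[revChrom]]
    el <- GRanges(revChrom,
                  IRanges(pmax(start(ref$tss)[onRev] - 1000L, 201L),
                          pmin(start(ref$tss)[onRev] + 999L, sl - 200L)))
    mpr <- mapIntervals(el, pair$chainSet)
    expect_true(all(mpr$mapped))
    expect_true(all(mpr$tStrand == "-"))
    ovl <- countOverlaps(GRanges(mpr$tName, IRanges(mpr$tStart, mpr$tEnd)),
                         pair$targetElements)
    expect_true(all(ovl >= 1L))
})

test_that("orthology is one2one with a planted DE slice", {
    cfg <- SyntheticConfig(seed = 6L, deEffectLog2 = 2)
    ref <- generateReference(cfg, withSequence = FALSE)
    pair <- generateChainPair(cfg, ref)
    expect_true(all(pair$orthology$homology_type == "one2one"))
    expect_equal(anyDuplicated(pair$orthology$gene_source), 0L)
    de <- applyDeThresholds(pair$deTable, computeFdr = TRUE)
    got <- de$records$direction
    expect_identical(got, pair$deTruth$direction)
    expect_equal(sum(got != "ns"),
                 max(1L, round(0.1 * nrow(pair$orthology))))
})

test_that("PWM generator is seeded and rows renormalize", {
    p1 <- generatePWMSet(c("T1", "T2"), seed = 11L)
    p2 <- generatePWMSet(c("T1", "T2"), seed = 11L)
    expect_identical(p1, p2)
    expect_true(all(abs(rowSums(p1$pwms$T1) - 1) < 1e-12))
    # uniform PWM scores zero under uniform background
    uni <- matrix(0.25, 5, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
    sc <- scanPWM("ACGTACGTA", uni, threshold = -1)
    expect_true(all(abs(sc$score) < 1e-12))
})

test_that("state segments plant the configured regulatory fraction", {
    si <- Seqinfo("t_chr1", 500000L)
    el <- GRanges("t_chr1", IRanges(seq(1001, 400001, by = 2500),
                                    width = 2000L))
    st <- generateStateSegments(el, si, seed = 21L,
                                fracRegulatory = 0.78)
    ov <- overlayChromatinStates(el, st$segments,
                                 defaultStateCategoryMap())
    expect_identical(ov$regulatoryAny, st$plantedRegulatory)
    expect_equal(mean(ov$regulatoryAny), 0.78, tolerance = 0.06)
    # the primary tissue contributes the most regulatory calls
    expect_equal(names(which.max(ov$perTissue)), "kidney")
})

test_that("written synthetic bundles are byte-identical across runs", {
    cfg <- SyntheticConfig(seed = 8L, nChroms = 1L, chromLen = 500000L,
                           nGenes = 20L, nH3K4me3 = 15L, nH3K27ac = 40L)
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    runSimulate(d1, cfg)
    runSimulate(d2, cfg)
    f1 <- list.files(d1, recursive = TRUE)
    expect_identical(f1, list.files(d2, recursive = TRUE))
    for (f in f1)
        expect_identical(readLines(file.path(d1, f), warn = FALSE),
                         readLines(file.path(d2, f), warn = FALSE),
                         info = f)
    # and the emitted formats read back to the same objects
    pk <- readPeaks(file.path(d1, "h3k27ac.narrowPeak"), "H3K27ac")
    expect_length(pk, 40L)
    tr <- readCoverageTrack(file.path(d1, "ip_h3k27ac.bedGraph"))
    expect_equal(totalReads(tr), 1e6)
    expect_equal(
        seqlengths(readChromSizes(file.path(d1, "chrom.sizes"))),
        seqlengths(generateReference(cfg, withSequence = FALSE)$seqinfo))
})
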