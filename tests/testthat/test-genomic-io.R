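# Format readers/writers: coordinate conventions, validation, round-trips.

test_that("narrowPeak summit offset and p-value decoding follow the format", {
    f <- withr::local_tempfile(fileext = ".narrowPeak")
    writeLines(c("chr1\t100\t600\tpk1\t0\t.\t5.5\t2.0\t1.25\t50",
                 "chr1\t1000\t1400\tpk2\t0\t.\t3.0\t8.0\t-1\t100"),
               f)
    pk <- readPeaks(f, mark = "H3K4me3")
    # BED start 100 is 1-based 101; summit offset 50 names base 150
    # (0-based), i.e. 151 in the internal 1-based convention
    expect_equal(start(pk), c(101L, 1001L))
    expect_equal(pk$summit, c(151L, 1101L))
    expect_equal(pk$pvalue, c(0.01, 1e-8))
    expect_equal(pk$rpmIP, c(5.5, 3.0))
    expect_equal(pk$rpmInput, c(1.25, NA))
    expect_equal(pk$mark, c("H3K4me3", "H3K4me3"))
})

test_that("broadPeak records get the midpoint summit", {
    f <- withr::local_tempfile(fileext = ".broadPeak")
    writeLines("chr1\t0\t10\tbp1\t0\t.\t2.0\t3.0\t1.0", f)
    pk <- readPeaks(f)
    # half-open [0,10) has midpoint base 5 (0-based) = 6 (1-based)
    expect_equal(pk$summit, 6L)
    expect_equal(width(pk), 10L)
})

test_that("malformed peak files are rejected with a line number", {
    f <- withr::local_tempfile(fileext = ".narrowPeak")
    writeLines(c("chr1\t100\t600\tpk1\t0\t.\t5.5\t2.0\t1.25\t50",
                 "chr1\t700\t900\tbad\t0\t.\t1.0"), f)
    expect_error(readPeaks(f), "line 2")
    f2 <- withr::local_tempfile(fileext = ".narrowPeak")
    writeLines("chr1\t100\t600\tpk1\t0\t.\t5.5\t2.0\t1.25\t900", f2)
    expect_error(readPeaks(f2), "summit outside")
})

test_that("peaks round-trip through narrowPeak", {
    pk <- makePeaks("chr1", c(1001, 5001), c(2000, 6000),
                    summit = c(1500, 5600), rpmIP = c(12.5, 7.25),
                    rpmInput = c(2.5, 1.125), pvalue = c(1e-6, 1e-3))
    f <- withr::local_tempfile(fileext = ".narrowPeak")
    writePeaks(pk, f)
    back <- readPeaks(f, mark = "H3K27ac")
    expect_equal(start(back), start(pk))
    expect_equal(end(back), end(pk))
    expect_equal(back$summit, pk$summit)
    expect_equal(back$rpmIP, pk$rpmIP, tolerance = 1e-7)
    expect_equal(back$rpmInput, pk$rpmInput, tolerance = 1e-7)
    expect_equal(back$pvalue, pk$pvalue, tolerance = 1e-7)
})

test_that("chain files parse, validate and round-trip", {
    cs <- makeChainSet(
        list(id = "1", score = 100, sName = "chr1", sSize = 1000L,
             sStart = 0L, sEnd = 1000L, tName = "tchr1", tSize = 1000L,
             tStrand = "+", tStart = 0L, tEnd = 1000L,
             size = 1000L, dt = integer(), dq = integer()),
        list(id = "2", score = 90, sName = "chr2", sSize = 500L,
             sStart = 100L, sEnd = 400L, tName = "tchr2", tSize = 600L,
             tStrand = "-", tStart = 50L, tEnd = 370L,
             size = c(100L, 180L), dt = 20L, dq = 40L),
        sourceLens = c(chr1 = 1000L, chr2 = 500L),
        targetLens = c(tchr1 = 1000L, tchr2 = 600L))
    f <- withr::local_tempfile(fileext = ".chain")
    writeChain(cs, f)
    back <- readChain(f)
    expect_length(chains(back), 2L)
    ch1 <- chains(back)[[1L]]
    expect_equal(ch1$size, 1000L)
    expect_length(ch1$dt, 0L)
    ch2 <- chains(back)[[2L]]
    expect_equal(ch2$tStrand, "-")
    expect_equal(ch2$size, c(100L, 180L))
    expect_equal(ch2$blockSrcStart, c(100L, 220L))
    expect_equal(ch2$blockTgtStart, c(50L, 190L))
})

test_that("invalid chain files are rejected with the chain id", {
    f <- withr::local_tempfile(fileext = ".chain")
    # declared source span 0-1000 but blocks sum to 900
    writeLines(c("chain 100 chr1 1000 + 0 1000 tchr1 1000 + 0 1000 7",
                 "900", ""), f)
    expect_error(readChain(f), "7")
    f2 <- withr::local_tempfile(fileext = ".chain")
    writeLines("chain 100 chr1 1000 + 0 1000 tchr1 1000 + 0 1000 9", f2)
    expect_error(readChain(f2), "truncated")
})

test_that("TSS derivation is strand-aware and GTF coordinates convert", {
    f <- withr::local_tempfile(fileext = ".gtf")
    writeLines(c(
        "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tgene_id \"gA\";",
        "chr1\tsrc\tgene\t1001\t2000\t.\t-\t.\tgene_id \"gB\";"), f)
    tss <- readTSS(f)
    # 1-based 1001 is 0-based 1000; minus strand TSS at 0-based 1999
    expect_equal(start(tss), c(1001L, 2000L))
    expect_equal(tss$gene_id, c("gA", "gB"))

    fb <- withr::local_tempfile(fileext = ".bed")
    writeLines("chr1\t1000\t2000\tgC\t0\t.", fb)
    expect_error(readTSS(fb), "strand")
})

test_that("gene GTF written by the generator reads back to the same TSS", {
    ref <- generateReference(SyntheticConfig(seed = 3L, nGenes = 20L))
    f <- withr::local_tempfile(fileext = ".gtf")
    writeGenesGtf(ref$genes, f)
    tss <- readTSS(f)
    expect_equal(start(tss), start(ref$tss))
    expect_equal(tss$gene_id, ref$tss$gene_id)
})

test_that("coverage tracks round-trip with their library size", {
    tr <- trackFromVector(c(0, 1.5, 2.25, 0, 4), total = 2e6)
    f <- withr::local_tempfile(fileext = ".bedGraph")
    writeCoverageTrack(tr, f)
    back <- readCoverageTrack(f)
    expect_equal(totalReads(back), 2e6)
    expect_equal(coverageRanges(back)$score,
                 coverageRanges(tr)$score, tolerance = 1e-9)
    # headerless bedGraph is rejected: RPM needs a declared library size
    f2 <- withr::local_tempfile(fileext = ".bedGraph")
    writeLines("chr1\t0\t10\t5", f2)
    expect_error(readCoverageTrack(f2), "totalReads")
})

test_that("PWM text round-trips with row normalization", {
    pw <- generatePWMSet(c("TFA", "TFB"), seed = 5L, width = 8L)
    f <- withr::local_tempfile(fileext = ".meme")
    writePWMSet(pw$pwms, f)
    back <- readPWMSet(f)
    expect_named(back, c("TFA", "TFB"))
    expect_true(all(abs(rowSums(back$TFA) - 1) < 1e-6))
    expect_equal(unname(back$TFA), unname(pw$pwms$TFA), tolerance = 1e-3)
    # degenerate all-zero position is a validation error
    bad <- matrix(c(1, 0, 0, 0, 0, 0, 0, 0), 2L, 4L, byrow = TRUE)
    expect_error(CREconserve:::normalizePWM(bad), "degenerate")
})

test_that("state segments, expression and orthology tables round-trip", {
    seg <- GRanges("chr1", IRanges(c(1, 101), c(100, 300)))
    seg$state <- c("EnhA1", "Quies")
    seg$tissue <- "kidney"
    f <- withr::local_tempfile(fileext = ".bed")
    writeStateSegments(seg, f)
    back <- readStateSegments(f)
    expect_equal(start(back), start(seg))
    expect_equal(back$state, seg$state)
    # overlapping segments within one tissue are invalid
    writeLines(c("chr1\t0\t100\tQuies\tkidney",
                 "chr1\t50\t150\tQuies\tkidney"), f)
    expect_error(readStateSegments(f), "overlap")

    m <- matrix(c(1.5, 2, 3, 4.25), 2L,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
    fe <- withr::local_tempfile(fileext = ".tsv")
    writeExpression(m, fe)
    expect_equal(readExpression(fe), m)

    fo <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("gene_source\tgene_target\thomology_type",
                 "g1\th1\tone2one", "g2\th2\tone2many"), fo)
    orth <- readOrthology(fo)
    expect_equal(orth$gene_source, "g1")
})
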