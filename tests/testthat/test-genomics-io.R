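test_that("BED and GTF annotation readers honour coordinate conventions", {
    bed <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t100\t600\tgeneA\t0\t+",
                 "chr1\t100\t600\tgeneB\t0\t-"), bed)
    gm <- readAnnotation(bed, "bed12", chromSizes = c(chr1 = 1000L))
    g <- genes(gm)
    ## BED 0-based half-open [100, 600) is internal 1-based closed [101, 600]
    expect_equal(start(g), c(101L, 101L))
    expect_equal(end(g), c(600L, 600L))
    tss <- tssPositions(gm)
    expect_equal(unname(tss[["geneA"]]), 101L)  # + strand: gene start
    expect_equal(unname(tss[["geneB"]]), 600L)  # - strand: gene end

    gtf <- tempfile(fileext = ".gtf")
    writeLines(c('chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "gA";',
                 'chr1\tsrc\texon\t501\t600\t.\t+\t.\tgene_id "gA";'), gtf)
    gm2 <- readAnnotation(gtf, "gtf")
    g2 <- genes(gm2)
    expect_equal(start(g2), 101L)   # GTF is already 1-based
    expect_equal(end(g2), 600L)
    expect_equal(S4Vectors::mcols(g2)$exonic_length, 200L)
})

test_that("annotation errors name the problem", {
    bad <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t100\t600\tgeneA\t0\t+", "chr1\t700"), bad)
    expect_error(readAnnotation(bad, "bed12"), "line 2")
    oob <- tempfile(fileext = ".bed")
    writeLines("chr1\t100\t600\tgeneA\t0\t+", oob)
    expect_error(readAnnotation(oob, "bed12", chromSizes = c(chr1 = 500L)),
                 "bounds|outside")
})

test_that("annotation round-trips through BED12 losslessly", {
    spec <- syntheticSpec(nChroms = 1L, chromLength = 200000L,
                          nGenes = 15L, seed = 9)
    gm <- makeGenome(spec)
    f <- tempfile(fileext = ".bed")
    writeAnnotation(gm, f)
    back <- readAnnotation(f, "bed12", chromSizes = chromSizes(gm))
    g0 <- genes(gm); g1 <- genes(back)
    expect_equal(start(g1), start(g0))
    expect_equal(end(g1), end(g0))
    expect_equal(as.character(strand(g1)), as.character(strand(g0)))
    expect_equal(S4Vectors::mcols(g1)$exonic_length,
                 S4Vectors::mcols(g0)$exonic_length)
    expect_equal(tssPositions(back), tssPositions(gm))
})

test_that("read interval reader validates against chromosome sizes", {
    empty <- tempfile(fileext = ".bed")
    writeLines(character(0), empty)
    expect_length(suppressMessages(readReads(empty)), 0L)

    f <- tempfile(fileext = ".bed")
    writeLines(sprintf("chr1\t%d\t%d", 0:99 * 10, 0:99 * 10 + 50), f)
    rd <- suppressMessages(readReads(f, chromSizes = c(chr1 = 2000L)))
    expect_length(rd, 100L)

    oob <- tempfile(fileext = ".bed")
    writeLines("chr1\t100\t900", oob)
    expect_error(suppressMessages(readReads(oob, chromSizes = c(chr1 = 500L))),
                 "bounds")
    unk <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t0\t50", "chrX\t0\t50"), unk)
    expect_error(suppressMessages(readReads(unk, chromSizes = c(chr1 = 100L))),
                 "absent")
    expect_warning(
        rd2 <- suppressMessages(readReads(unk, chromSizes = c(chr1 = 100L),
                                          unknownChrom = "skip")),
        "skipping")
    expect_length(rd2, 1L)
})

test_that("bedGraph writer merges runs and round-trips exactly", {
    ## constant track: one merged line per chromosome
    tr <- trackFromValues(list(chr1 = rep(2, 10), chr2 = rep(3, 5)),
                          binSize = 100L)
    f <- tempfile(fileext = ".bedGraph")
    writeTrack(tr, f)
    expect_length(readLines(f), 2L)

    ## random track round-trip at the declared 6-significant-digit precision
    set.seed(1)
    v <- list(chr1 = runif(50) * 10, chr2 = c(rep(0, 10), runif(10)))
    tr2 <- trackFromValues(v, binSize = 100L)
    f2 <- tempfile(fileext = ".bedGraph")
    writeTrack(tr2, f2)
    back <- readTrack(f2, 100L, chromSizes(tr2))
    expect_equal(trackValues(back)$chr1, signif(v$chr1, 6))
    expect_equal(trackValues(back)$chr2, signif(v$chr2, 6))

    ## zero regions written explicitly: genome-wide mean survives the trip
    expect_equal(trackMean(back), mean(signif(unlist(v), 6)))

    ## all-zero chromosome still covered by a single zero interval
    tr3 <- trackFromValues(list(chr1 = rep(0, 8)), binSize = 100L)
    f3 <- tempfile(fileext = ".bedGraph")
    writeTrack(tr3, f3)
    expect_length(readLines(f3), 1L)
    expect_true(grepl("\t0$", readLines(f3)))
})

test_that("calibration table reader enforces the reference invariants", {
    ok <- tempfile()
    writeLines(c("sample_id\tmark\tglobal_level",
                 "ref\tH3K36me2\t1.0", "mut\tH3K36me2\t0.4"), ok)
    cal <- readCalibration(ok)
    expect_equal(globalLevel(cal, "mut", "H3K36me2"), 0.4)
    expect_equal(referenceSample(cal, "H3K36me2"), "ref")

    zero <- tempfile()
    writeLines(c("sample_id\tmark\tglobal_level",
                 "ref\tm\t1.0", "mut\tm\t0"), zero)
    expect_error(readCalibration(zero), "> 0")

    dup <- tempfile()
    writeLines(c("sample_id\tmark\tglobal_level",
                 "ref\tm\t1.0", "ref\tm\t1.0"), dup)
    expect_error(readCalibration(dup), "duplicate|reference")

    noref <- tempfile()
    writeLines(c("sample_id\tmark\tglobal_level",
                 "a\tm\t0.5", "b\tm\t0.7"), noref)
    expect_error(readCalibration(noref), "reference")
})

test_that("expression and partition tables round-trip losslessly", {
    cnt <- matrix(c(10L, 0L, 7L, 3L, 25L, 1L, 0L, 9L), 4, 2,
                  dimnames = list(paste0("g", 1:4), c("s1", "s2")))
    et <- ExpressionTable(cnt, exonicLength = c(1000, 2000, 1500, 800),
                          librarySize = c(s1 = 2e6, s2 = 1e6))
    f <- tempfile(fileext = ".tsv")
    writeExpression(et, f)
    back <- readExpression(f)
    expect_equal(SummarizedExperiment::assay(back, "counts"),
                 SummarizedExperiment::assay(et, "counts"))
    expect_equal(librarySizes(back), librarySizes(et))
    expect_equal(exonicLengths(back), exonicLengths(et))

    part <- GenePartition("regulation",
                          list(up = c("g1", "g3"), down = "g2",
                               unchanged = "g4"),
                          params = list(threshold = 2, pseudocount = 0.5))
    pf <- tempfile(fileext = ".tsv")
    writePartition(part, pf)
    pback <- readPartition(pf)
    expect_equal(scheme(pback), "regulation")
    expect_setequal(partitionSets(pback)$up, c("g1", "g3"))
    expect_equal(partitionParams(pback)$threshold, 2)
})
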