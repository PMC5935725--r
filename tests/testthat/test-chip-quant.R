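test_that("binned coverage matches its definition and a per-base oracle", {
    gm <- genomeFromGenes(2000L, 100L, 300L)
    ## one 100 bp read fully inside a 200 bp bin
    r <- GRanges("chr1", IRanges(251, 350))
    tr <- computeCoverage(r, gm, 200L)
    v <- trackValues(tr)$chr1
    expect_equal(v[2], 0.5)
    expect_equal(sum(v), 0.5)
    ## read straddling two bins 60/40 (bin size 100)
    r2 <- GRanges("chr1", IRanges(141, 240))
    v2 <- trackValues(computeCoverage(r2, gm, 100L))$chr1
    expect_equal(v2[2:3], c(0.6, 0.4))

    ## random fixture against the brute-force per-base oracle
    set.seed(21)
    starts <- sample.int(1900L, 200L, replace = TRUE)
    rr <- GRanges("chr1", IRanges(starts, pmin(starts + 49L, 2000L)))
    for (bs in c(1L, 100L, 150L)) {
        got <- trackValues(computeCoverage(rr, gm, bs))$chr1
        expect_equal(got, coverageOracle(rr, 2000L, bs), info = bs)
    }
})

test_that("per-nucleotide coverage aggregated to k equals direct binning", {
    gm <- genomeFromGenes(1950L, 100L, 300L)  # ragged final bin
    set.seed(8)
    starts <- sample.int(1900L, 150L, replace = TRUE)
    rr <- GRanges("chr1", IRanges(starts, pmin(starts + 74L, 1950L)))
    fine <- computeCoverage(rr, gm, 1L)
    for (k in c(50L, 200L)) {
        direct <- computeCoverage(rr, gm, k)
        expect_equal(trackValues(rebinTrack(fine, k))$chr1,
                     trackValues(direct)$chr1, info = k)
    }
})

test_that("unit-mean scaling normalizes, preserves ratios, rejects zeros", {
    tr <- trackFromValues(list(chr1 = c(2, 4, 6)), binSize = 100L)
    s <- scaleToUnitMean(tr)
    expect_equal(trackValues(s)$chr1, c(0.5, 1.0, 1.5))
    ## idempotence
    expect_equal(trackValues(scaleToUnitMean(s))$chr1,
                 trackValues(s)$chr1)
    ## any random positive track
    set.seed(2)
    for (i in 1:5) {
        v <- list(chr1 = rexp(100) + 0.01, chr2 = rexp(40) + 0.01)
        s2 <- scaleToUnitMean(trackFromValues(v, 50L))
        expect_lt(abs(trackMean(s2) - 1), 1e-12)
        ## monotone: bin ranking unchanged
        expect_equal(order(unlist(trackValues(s2))), order(unlist(v)))
    }
    expect_error(scaleToUnitMean(trackFromValues(list(chr1 = c(0, 0)), 100L)),
                 "all-zero")
})

test_that("Poisson subtraction follows the quantile rule exactly", {
    ## chip = 10 reads in a bin, background lambda = 2, pUpper = 0.001:
    ## the enumerated 99.9% Poisson quantile of 2 is 8, so 2 read units
    ## survive.  depth converts between scaled intensity and read units.
    expect_equal(poissonUpperOracle(2, 0.001), 8L)
    depth <- 2                # depth-matched input rate: lambda = 1 * 2
    chip <- trackFromValues(list(chr1 = c(10, 5, 0, 3) / depth), 100L)
    input <- trackFromValues(list(chr1 = rep(1, 4)), 100L)  # unit mean
    out <- subtractInput(chip, input, subtractionParams(pUpper = 0.001),
                         depth = depth)
    got_reads <- trackValues(out)$chr1 * depth
    expect_equal(got_reads, pmax(c(10, 5, 0, 3) - 8, 0))

    ## lambda = 0 leaves chip unchanged
    z <- trackFromValues(list(chr1 = rep(1, 4)), 100L)
    zin <- trackFromValues(list(chr1 = rep(0, 4)), 100L)
    expect_warning(out0 <- subtractInput(z, zin, depth = 5), "all-zero")
    expect_equal(trackValues(out0)$chr1, rep(1, 4))

    ## chip below the bound floors at 0
    low <- trackFromValues(list(chr1 = rep(1, 4)), 100L)
    hi_in <- trackFromValues(list(chr1 = rep(1, 4)), 100L)
    outf <- subtractInput(low, hi_in, depth = 100)
    expect_true(all(trackValues(outf)$chr1 == 0))

    ## mismatched grids are errors
    other <- trackFromValues(list(chr1 = rep(1, 8)), 50L)
    expect_error(subtractInput(z, other, depth = 5), "grid")
})

test_that("subtraction matches the exhaustive CDF oracle on a fixture", {
    set.seed(31)
    n <- 2000L
    depth <- 5
    chip_reads <- rpois(n, 8)
    input_reads <- rpois(n, 5)
    chip <- scaleToUnitMean(trackFromValues(list(chr1 = as.numeric(chip_reads)),
                                            200L, nReads = sum(chip_reads)))
    input <- scaleToUnitMean(trackFromValues(list(chr1 = as.numeric(input_reads)),
                                             200L))
    params <- subtractionParams(pUpper = 0.001)
    out <- subtractInput(chip, input, params)
    d <- sum(chip_reads) / n
    lam <- trackValues(input)$chr1 * d
    u <- poissonUpperOracle(lam, params$pUpper)
    expected <- pmax(trackValues(chip)$chr1 - u / d, 0)
    expect_identical(trackValues(out)$chr1, expected)
})

test_that("global calibration rescales to the measured level", {
    cal <- CalibrationTable(data.frame(
        sample_id = c("ref", "mut"), mark = "H3K36me2",
        global_level = c(1.0, 0.4)))
    mk <- function(id) {
        tr <- trackFromValues(list(chr1 = rep(1, 10)), 100L, sampleId = id,
                              mark = "H3K36me2")
        tr
    }
    out <- applyGlobalCalibration(mk("mut"), cal)
    expect_equal(trackMean(out), 0.4)
    expect_equal(trackMeta(out)$calibration$level, 0.4)
    ## reference sample is the identity
    ref <- applyGlobalCalibration(mk("ref"), cal)
    expect_equal(trackValues(ref)$chr1, rep(1, 10))
    ## calibration is monotone in the bins
    set.seed(4)
    v <- runif(10)
    tr <- trackFromValues(list(chr1 = v), 100L, sampleId = "mut",
                          mark = "H3K36me2")
    expect_equal(order(trackValues(applyGlobalCalibration(tr, cal))$chr1),
                 order(v))
    expect_error(applyGlobalCalibration(mk("nobody"), cal), "no calibration")
})

test_that("gene-body means are overlap-weighted and match a per-base oracle", {
    gm <- genomeFromGenes(2000L, c(101L, 901L), c(700L, 1100L))
    ## constant track: every gene mean equals the constant
    const <- trackFromValues(list(chr1 = rep(3.3, 10)), 200L)
    gb <- geneBodySignal(const, gm)
    expect_equal(gb$mean_signal, c(3.3, 3.3))

    ## single-bin gene picks that bin's value
    gm1 <- genomeFromGenes(2000L, 401L, 600L)
    v <- c(1, 5, 9, 2, 4, 8, 7, 3, 6, 10)
    tr <- trackFromValues(list(chr1 = v), 200L)
    expect_equal(geneBodySignal(tr, gm1)$mean_signal, 9)

    ## random fixture vs per-base expansion oracle
    set.seed(12)
    vv <- runif(10) * 4
    trr <- trackFromValues(list(chr1 = vv), 200L)
    gm2 <- genomeFromGenes(2000L, c(151L, 1001L), c(850L, 1999L))
    got <- geneBodySignal(trr, gm2)$mean_signal
    perbase <- rep(vv, each = 200L)
    oracle <- c(mean(perbase[151:850]), mean(perbase[1001:1999]))
    expect_equal(got, oracle)

    ## gene on a chromosome the track does not cover
    expect_error(geneBodySignal(trackFromValues(list(chr2 = rep(1, 10)), 200L),
                                genomeFromGenes(2000L, 101L, 300L)),
                 "absent")
})
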