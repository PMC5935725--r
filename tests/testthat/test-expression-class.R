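test_that("RPKM follows its definition", {
    cnt <- matrix(c(10L, 0L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
    et <- ExpressionTable(cnt, exonicLength = c(1000, 500),
                          librarySize = 1e6)
    r <- rpkm(computeRPKM(et))
    expect_equal(r["g1", "s1"], 10)
    expect_equal(r["g2", "s1"], 0)
    ## doubling library size halves RPKM
    et2 <- ExpressionTable(cnt, exonicLength = c(1000, 500),
                           librarySize = 2e6)
    expect_equal(rpkm(computeRPKM(et2))["g1", "s1"], 5)
    ## invalid containers are rejected
    expect_error(ExpressionTable(cnt, exonicLength = c(0, 500),
                                 librarySize = 1e6), "exonic_length")
    expect_error(ExpressionTable(cnt, exonicLength = c(1000, 500),
                                 librarySize = 5), "library_size")
})

test_that("twofold calls follow the thresholded ratio rule", {
    m <- rbind(g_up = c(1, 4), g_down = c(4, 1), g_flat = c(3, 3),
               g_zero = c(0, 5))
    colnames(m) <- c("from", "to")
    et <- computeRPKM(exprFromRPKM(m))
    p0 <- callRegulated(et, "from", "to", threshold = 2, pseudocount = 0)
    s0 <- partitionSets(p0)
    expect_true("g_up" %in% s0$up)
    expect_true("g_down" %in% s0$down)
    expect_true("g_flat" %in% s0$unchanged)
    ## zero-baseline gene becomes callable with the pseudocount:
    ## (5 + 0.5) / (0 + 0.5) = 11 >= 2
    p5 <- callRegulated(et, "from", "to", threshold = 2, pseudocount = 0.5)
    expect_true("g_zero" %in% partitionSets(p5)$up)
    expect_error(callRegulated(et, "from", "nowhere"), "not found")
    expect_error(callRegulated(et, "from", "to", threshold = 1), "threshold")
})

test_that("regulation partitions are complete and symmetric", {
    set.seed(10)
    for (i in 1:5) {
        m <- matrix(round(rexp(60, 0.2)), 30, 2,
                    dimnames = list(sprintf("g%02d", 1:30), c("a", "b")))
        et <- computeRPKM(exprFromRPKM(m))
        fwd <- partitionSets(callRegulated(et, "a", "b"))
        expect_setequal(unlist(fwd), rownames(m))        # completeness
        rev <- partitionSets(callRegulated(et, "b", "a"))
        expect_setequal(fwd$up, rev$down)                # symmetry
        expect_setequal(fwd$down, rev$up)
        expect_setequal(fwd$unchanged, rev$unchanged)
    }
})

test_that("pseudocount perturbs only genes near zero or the threshold", {
    set.seed(14)
    for (i in 1:5) {
        m <- matrix(round(rexp(80, 0.1)), 40, 2,
                    dimnames = list(sprintf("g%02d", 1:40), c("a", "b")))
        et <- computeRPKM(exprFromRPKM(m))
        c0 <- partitionSets(callRegulated(et, "a", "b", pseudocount = 0))
        c5 <- partitionSets(callRegulated(et, "a", "b", pseudocount = 0.5))
        ## monotonicity: the pseudocount can soften a call towards
        ## unchanged but never flips up to down or vice versa
        expect_length(intersect(c0$up, c5$down), 0L)
        expect_length(intersect(c0$down, c5$up), 0L)
        ## with both values >= 10 * c the ratio moves by at most a
        ## factor 1.1, so calls are identical away from the threshold
        r <- rpkm(et)
        ratio <- (r[, "b"] + 0.01) / (r[, "a"] + 0.01)
        far <- ratio >= 2.2 | ratio <= 1 / 2.2 |
            (ratio <= 2 / 1.1 & ratio >= 1.1 / 2)
        safe <- rownames(m)[r[, "a"] >= 5 & r[, "b"] >= 5 & far]
        for (set in c("up", "down", "unchanged"))
            expect_setequal(intersect(c0[[set]], safe),
                            intersect(c5[[set]], safe))
    }
})

test_that("sensitivity partition splits the induced set per the rule", {
    m <- rbind(gA = c(1, 4, 1, 1.5),   # induced in WT, flat in mutant
               gB = c(1, 4, 1, 4),     # induced in both
               gC = c(2, 2, 2, 2))     # not induced anywhere
    colnames(m) <- c("WT_D0", "WT_D2", "MUT_D0", "MUT_D2")
    et <- computeRPKM(exprFromRPKM(m, length_bp = 2000))
    up <- callRegulated(et, "WT_D0", "WT_D2", pseudocount = 0)
    expect_setequal(partitionSets(up)$up, c("gA", "gB"))
    sens <- partitionSensitivity(up, et, "MUT_D0", "MUT_D2",
                                 pseudocount = 0)
    expect_setequal(partitionSets(sens)$sensitive, "gA")
    expect_setequal(partitionSets(sens)$resistant, "gB")
    ## sensitive and resistant always cover the input up set
    expect_setequal(unname(unlist(partitionSets(sens))),
                    partitionSets(up)$up)
    ## level reading: mutant end level below control end level / T
    sl <- partitionSensitivity(up, et, "MUT_D0", "MUT_D2", pseudocount = 0,
                               rule = "level", controlTo = "WT_D2")
    expect_setequal(partitionSets(sl)$sensitive, "gA")
    expect_warning(p0 <- partitionSensitivity(character(0), et,
                                              "MUT_D0", "MUT_D2"),
                   "empty")
    expect_length(unlist(partitionSets(p0)), 0L)
})

test_that("set overlap performs exact set algebra", {
    ov <- overlapSets(c("a", "b", "c"), c("b", "c", "d"))
    expect_setequal(ov$shared, c("b", "c"))
    expect_setequal(ov$aOnly, "a")
    expect_setequal(ov$bOnly, "d")
    expect_equal(unname(ov$counts), c(1L, 2L, 1L))
    expect_length(overlapSets(c("x", "y"), c("p", "q"))$shared, 0L)
    expect_length(overlapSets(c("a"), c("a", "b"))$aOnly, 0L)
})

test_that("selectivity ranking is ordered, capped and deterministic", {
    m <- cbind(A = c(8, 4, 0.5, 0.0625), B = c(1, 1, 1, 1))
    rownames(m) <- c("hi", "mid", "lo", "lowest")
    et <- computeRPKM(exprFromRPKM(m, length_bp = 16000))
    rk <- rankSelectivity(et, "A", "B", topN = 1L, pseudocount = 0)
    expect_equal(selectedGenes(rk, "A"), "hi")
    expect_equal(selectedGenes(rk, "B"), "lowest")
    tb <- rankingTable(rk)
    expect_equal(tb$gene_id, c("hi", "mid", "lo", "lowest"))
    expect_equal(tb$log2fc[1], 3)

    ## degenerate all-equal case warns
    m2 <- cbind(A = rep(2, 4), B = rep(2, 4))
    rownames(m2) <- paste0("g", 1:4)
    et2 <- computeRPKM(exprFromRPKM(m2))
    expect_warning(rankSelectivity(et2, "A", "B", topN = 1L), "degenerate")
    ## topN beyond the gene count warns and truncates
    w <- capture_warnings(rk3 <- rankSelectivity(et, "A", "B", topN = 10L))
    expect_true(any(grepl("topN|overlap", w)))
    expect_lte(length(selectedGenes(rk3, "A")), 2L)
})

test_that("heatmap matrices are exact log2 fold changes", {
    m <- cbind(s1 = c(4, 1, 2), s2 = c(1, 4, 2))
    rownames(m) <- c("g1", "g2", "g3")
    et <- computeRPKM(exprFromRPKM(m))
    hm <- heatmapMatrix(et, list(c("s1", "s2")), pseudocount = 0)
    expect_equal(unname(hm[, 1]), c(2, -2, 0))
    ## self-contrast is identically zero
    hm0 <- heatmapMatrix(et, list(c("s1", "s1")), pseudocount = 0)
    expect_true(all(hm0 == 0))
    expect_error(heatmapMatrix(et, list(c("s1", "nope"))), "not found")
    ## rows follow the ranking and serialize losslessly
    rk <- rankSelectivity(et, "s1", "s2", topN = 1L, pseudocount = 0)
    hm2 <- heatmapMatrix(et, list(c("s1", "s2")), ranking = rk,
                         pseudocount = 0)
    expect_equal(rownames(hm2), rankingTable(rk)$gene_id)
    f <- tempfile(fileext = ".tsv")
    write.table(data.frame(gene_id = rownames(hm2), hm2,
                           check.names = FALSE), f, sep = "\t",
                quote = FALSE, row.names = FALSE)
    back <- read.delim(f, check.names = FALSE)
    expect_equal(back[[2]], unname(hm2[, 1]))
})

test_that("fraction summaries report one-decimal percentages", {
    p <- GenePartition("regulation",
                       list(up = sprintf("u%04d", 1:1610),
                            down = sprintf("d%04d", 1:3348)))
    fr <- summarizeFractions(p, 17500)
    expect_equal(unname(fr["up"]), 9.2)
    expect_equal(unname(fr["down"]), 19.1)
    p0 <- GenePartition("x", list(up = character(0)))
    expect_equal(unname(summarizeFractions(p0, 10)["up"]), 0)
    pN <- GenePartition("x", list(all = paste0("g", 1:10)))
    expect_equal(unname(summarizeFractions(pN, 10)["all"]), 100)
    expect_error(summarizeFractions(p, 0), "totalGenes")
})
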