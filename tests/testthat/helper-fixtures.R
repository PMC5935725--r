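## Small in-code fixtures shared across test files.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
})

## A track built directly from value vectors (bypasses read simulation).
trackFromValues <- function(values, binSize = 200L, sampleId = "sample",
                            mark = "mark", condition = "condition",
                            nReads = NA_real_) {
    cs <- vapply(values, function(v) length(v) * binSize, numeric(1))
    SignalTrack(values, binSize, cs, sampleId = sampleId, mark = mark,
                condition = condition, nReads = nReads)
}

## A one-chromosome genome with explicitly placed genes.
genomeFromGenes <- function(chromLength, starts, ends,
                            strands = rep("+", length(starts)),
                            exonic = ends - starts + 1L) {
    g <- GRanges("chr1", IRanges(starts, ends), strand = strands)
    S4Vectors::mcols(g)$gene_id <- sprintf("g%03d", seq_along(starts))
    S4Vectors::mcols(g)$exonic_length <- as.integer(exonic)
    GenomeModel(c(chr1 = chromLength), g)
}

## Expression table from an RPKM-scale matrix at library size 1e6, so
## counts = rpkm * length_kb and RPKM round-trips up to integer rounding.
exprFromRPKM <- function(rpkm_mat, length_bp = 1000) {
    counts <- round(rpkm_mat * (length_bp / 1000))
    ExpressionTable(counts, exonicLength = rep(length_bp, nrow(rpkm_mat)),
                    librarySize = stats::setNames(rep(1e6, ncol(rpkm_mat)),
                                                  colnames(rpkm_mat)))
}

## Independent brute-force oracle: per-base coverage aggregated to bins.
coverageOracle <- function(reads, chromLength, binSize) {
    perbase <- numeric(chromLength)
    for (i in seq_along(reads)) {
        s <- start(reads)[i]; e <- min(end(reads)[i], chromLength)
        perbase[s:e] <- perbase[s:e] + 1
    }
    grp <- (seq_len(chromLength) - 1L) %/% binSize
    as.numeric(tapply(perbase, grp, sum)) / binSize
}

## Independent Poisson-quantile oracle: enumerate the CDF term by term.
poissonUpperOracle <- function(lambda, pUpper) {
    vapply(lambda, function(lam) {
        target <- 1 - pUpper
        k <- 0L
        cdf <- stats::dpois(0, lam)
        while (cdf < target) {
            k <- k + 1L
            cdf <- cdf + stats::dpois(k, lam)
        }
        k
    }, integer(1))
}
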