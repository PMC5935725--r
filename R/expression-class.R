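#' Compute RPKM from raw counts
#'
#' RPKM = counts / (exonic length in kb) / (library size in millions):
#' reads per kilobase of transcript per million mapped reads.
#'
#' @param x an [ExpressionTable-class] with positive exonic lengths and
#'   library sizes.
#' @return `x` with an `rpkm` assay added.
#' @aliases computeRPKM,ExpressionTable-method
#' @export
setMethod("computeRPKM", "ExpressionTable", function(x) {
    len <- exonicLengths(x)
    lib <- librarySizes(x)
    if (any(len <= 0)) stop("exonic lengths must be > 0")
    if (any(lib <= 0)) stop("library sizes must be > 0")
    cnt <- SummarizedExperiment::assay(x, "counts")
    SummarizedExperiment::assay(x, "rpkm") <-
        sweep(cnt / (len / 1000), 2, lib / 1e6, "/")
    x
})

## RPKM column for one sample, computing the assay on the fly if needed.
sampleRPKM <- function(x, sample) {
    if (!sample %in% colnames(x))
        stop("sample '", sample, "' not found in the expression table")
    if (!"rpkm" %in% SummarizedExperiment::assayNames(x))
        x <- computeRPKM(x)
    rpkm(x)[, sample]
}

#' Call up/down/unchanged genes by fold change
#'
#' A gene is up-regulated from `sampleFrom` to `sampleTo` when
#' `(to + c) / (from + c) >= T`, down-regulated when the ratio is
#' `<= 1/T`, and unchanged otherwise.  The default threshold `T = 2`
#' gives twofold calls; the pseudocount `c` makes zero-baseline genes
#' callable and is recorded in the partition parameters.
#'
#' @param x an [ExpressionTable-class].
#' @param sampleFrom,sampleTo sample (column) labels; missing samples
#'   are an error.
#' @param threshold fold threshold `T > 1` (default 2).
#' @param pseudocount RPKM pseudocount `c >= 0` (default 0.5).
#' @return A [GenePartition-class] with sets `up`, `down`, `unchanged`.
#' @export
callRegulated <- function(x, sampleFrom, sampleTo, threshold = 2,
                          pseudocount = 0.5) {
    stopifnot(threshold > 1, pseudocount >= 0)
    from <- sampleRPKM(x, sampleFrom)
    to <- sampleRPKM(x, sampleTo)
    ratio <- (to + pseudocount) / (from + pseudocount)
    ids <- rownames(x)
    GenePartition("regulation",
                  list(up = ids[ratio >= threshold],
                       down = ids[ratio <= 1 / threshold],
                       unchanged = ids[ratio > 1 / threshold &
                                       ratio < threshold]),
                  params = list(from = sampleFrom, to = sampleTo,
                                threshold = threshold,
                                pseudocount = pseudocount))
}

#' Split control-induced genes into mutant-sensitive and -resistant
#'
#' Given the genes up-regulated in the control comparison, a gene is
#' sensitive when it fails to be induced in the mutant and resistant
#' otherwise; the two sets always partition the input set.  Two readings
#' of "fails to be induced" are available: `rule = "fold"` (default)
#' requires the mutant's own fold change `(to + c)/(from + c)` to stay
#' below `T`; `rule = "level"` instead requires the mutant's final level
#' to stay below the control's final level divided by `T`.
#'
#' @param upInControl character vector of control-up gene ids (or a
#'   `GenePartition` from [callRegulated()], whose `up` set is used).
#' @param x an [ExpressionTable-class].
#' @param mutantFrom,mutantTo mutant sample labels.
#' @param threshold fold threshold `T` (same `T` as the control call).
#' @param pseudocount RPKM pseudocount.
#' @param rule `"fold"` or `"level"` (see above).
#' @param controlTo control final-timepoint sample, required for
#'   `rule = "level"`.
#' @return A [GenePartition-class] with sets `sensitive`, `resistant`;
#'   empty input yields an empty partition with a warning.
#' @export
partitionSensitivity <- function(upInControl, x, mutantFrom, mutantTo,
                                 threshold = 2, pseudocount = 0.5,
                                 rule = c("fold", "level"),
                                 controlTo = NULL) {
    rule <- match.arg(rule)
    if (is(upInControl, "GenePartition"))
        upInControl <- partitionSets(upInControl)$up
    upInControl <- as.character(upInControl)
    params <- list(mutantFrom = mutantFrom, mutantTo = mutantTo,
                   threshold = threshold, pseudocount = pseudocount,
                   rule = rule)
    if (length(upInControl) == 0L) {
        warning("empty up-regulated set: empty sensitivity partition")
        return(GenePartition("sensitivity",
                             list(sensitive = character(0),
                                  resistant = character(0)), params))
    }
    if (!all(upInControl %in% rownames(x)))
        stop("up-regulated gene(s) absent from the expression table")
    mfrom <- sampleRPKM(x, mutantFrom)[upInControl]
    mto <- sampleRPKM(x, mutantTo)[upInControl]
    if (rule == "fold") {
        induced <- (mto + pseudocount) / (mfrom + pseudocount) >= threshold
    } else {
        if (is.null(controlTo))
            stop("rule = 'level' requires controlTo")
        cto <- sampleRPKM(x, controlTo)[upInControl]
        induced <- mto >= cto / threshold
        params$controlTo <- controlTo
    }
    GenePartition("sensitivity",
                  list(sensitive = upInControl[!induced],
                       resistant = upInControl[induced]), params)
}

#' Three-way overlap of two gene sets
#'
#' @param a,b character vectors of gene ids (or `GenePartition` sets
#'   extracted beforehand).
#' @return list with `aOnly`, `shared`, `bOnly` and an integer `counts`
#'   vector; the counts always satisfy
#'   `aOnly + shared = length(unique(a))`.
#' @export
overlapSets <- function(a, b) {
    a <- unique(as.character(a))
    b <- unique(as.character(b))
    shared <- intersect(a, b)
    out <- list(aOnly = setdiff(a, b), shared = shared,
                bOnly = setdiff(b, a))
    out$counts <- c(aOnly = length(out$aOnly), shared = length(shared),
                    bOnly = length(out$bOnly))
    out
}

#' Rank genes by between-condition selectivity
#'
#' Computes `log2((A + c) / (B + c))` on RPKM per gene and selects the
#' `topN` most positive genes as A-selective and the `topN` most
#' negative as B-selective.  Ranking is deterministic: genes are ordered
#' by decreasing log2 fold change with ties broken by gene id, and the
#' stored `rank` follows that order.
#'
#' @param x an [ExpressionTable-class].
#' @param condA,condB sample labels to contrast.
#' @param topN selection size per direction (default 1000); if it
#'   exceeds half the gene count the selection is truncated with a
#'   warning.
#' @param pseudocount RPKM pseudocount.
#' @return A [SelectivityRanking-class].
#' @export
rankSelectivity <- function(x, condA, condB, topN = 1000L,
                            pseudocount = 0.5) {
    stopifnot(topN >= 1L)
    a <- sampleRPKM(x, condA)
    b <- sampleRPKM(x, condB)
    lfc <- log2((a + pseudocount) / (b + pseudocount))
    ids <- rownames(x)
    ord <- order(-lfc, ids)
    tb <- data.frame(gene_id = ids[ord], log2fc = lfc[ord],
                     rank = seq_along(ids), row.names = NULL)
    n <- nrow(tb)
    eff <- min(topN, n)
    if (topN > n)
        warning("topN exceeds gene count: selecting all ", n, " genes")
    if (2L * eff > n) {
        warning("selection sides overlap: truncating to ", n %/% 2L,
                " genes per direction")
        eff <- n %/% 2L
    }
    if (all(lfc == 0))
        warning("all log2 fold changes are 0: selection is degenerate")
    tb$selected <- NA_character_
    if (eff > 0L) {
        tb$selected[seq_len(eff)] <- "A"
        tb$selected[seq.int(n - eff + 1L, n)] <- "B"
    }
    new("SelectivityRanking", table = tb,
        labels = c(A = condA, B = condB), topN = as.integer(eff),
        pseudocount = pseudocount)
}

#' Log2 fold-change matrix for a heatmap
#'
#' One column per contrast `(A, B)` holding `log2((A + c)/(B + c))` on
#' RPKM, rows ordered by a [SelectivityRanking-class] (or by the
#' table's gene order when no ranking is given).
#'
#' @param x an [ExpressionTable-class].
#' @param contrasts list of two-element character vectors `c(A, B)`;
#'   unknown sample labels are an error.
#' @param ranking optional [SelectivityRanking-class] fixing row order.
#' @param pseudocount RPKM pseudocount.
#' @return numeric matrix, rownames gene ids, colnames `"A/B"`.
#' @export
heatmapMatrix <- function(x, contrasts, ranking = NULL,
                          pseudocount = 0.5) {
    stopifnot(is.list(contrasts), length(contrasts) >= 1L)
    order_ids <- if (is.null(ranking)) rownames(x)
                 else rankingTable(ranking)$gene_id
    cols <- lapply(contrasts, function(ct) {
        stopifnot(length(ct) == 2L)
        a <- sampleRPKM(x, ct[1])[order_ids]
        b <- sampleRPKM(x, ct[2])[order_ids]
        log2((a + pseudocount) / (b + pseudocount))
    })
    m <- do.call(cbind, cols)
    dimnames(m) <- list(order_ids,
                        vapply(contrasts, function(ct)
                            paste(ct, collapse = "/"), character(1)))
    m
}

#' Set sizes as percentages of a gene total
#'
#' @param partition a [GenePartition-class].
#' @param totalGenes denominator (> 0); must be at least as large as the
#'   partition's union.
#' @return named numeric vector of percentages, rounded to 1 decimal.
#' @export
summarizeFractions <- function(partition, totalGenes) {
    if (totalGenes <= 0) stop("totalGenes must be > 0")
    sizes <- lengths(partitionSets(partition))
    if (sum(sizes) > totalGenes)
        stop("totalGenes smaller than the partition union")
    round(100 * sizes / totalGenes, 1)
}
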