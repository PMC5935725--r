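#' @importFrom GenomicRanges coverage
#' @importFrom IRanges Views viewSums
NULL

#' Binned read coverage over a genome
#'
#' The value of a bin is the total overlap (in bases) between the reads
#' and the bin, divided by `binSize`; at `binSize = 1` this is the
#' per-nucleotide read coverage.  The final bin of a chromosome may be
#' shorter than `binSize` but is still divided by `binSize`.
#'
#' @param reads `GRanges` of read intervals.
#' @param genome a [GenomeModel-class] supplying the chromosome grid.
#' @param binSize bin width in bases (default 200, typical for broad
#'   histone marks).
#' @param sampleId,mark,condition labels for the resulting track.
#' @return A raw-coverage [SignalTrack-class]; `nReads` records the read
#'   count so the Poisson input subtraction can depth-match later.
#' @export
computeCoverage <- function(reads, genome, binSize = 200L,
                            sampleId = "sample", mark = "mark",
                            condition = "condition") {
    stopifnot(binSize >= 1L)
    cs <- chromSizes(genome)
    if (length(reads) &&
        any(!as.character(seqnames(reads)) %in% names(cs)))
        stop("reads on chromosomes absent from the genome")
    gr <- GRanges(factor(as.character(seqnames(reads)), levels = names(cs)),
                  IRanges(start(reads), end(reads)))
    GenomeInfoDb::seqlengths(gr) <- unname(cs)
    cov <- coverage(gr)
    vals <- lapply(names(cs), function(ch) {
        starts <- seq.int(1L, cs[[ch]], by = binSize)
        v <- Views(cov[[ch]], start = starts,
                   end = pmin(starts + binSize - 1L, cs[[ch]]))
        as.numeric(viewSums(v)) / binSize
    })
    names(vals) <- names(cs)
    SignalTrack(vals, binSize, cs, sampleId = sampleId, mark = mark,
                condition = condition, nReads = length(reads),
                meta = list(coverage = list(nReads = length(reads),
                                            binSize = as.integer(binSize))))
}

#' Scale a track so its genome-wide mean intensity is 1
#'
#' Multiplies every bin by (number of genome bins) / (total signal).
#' This removes sequencing-depth differences between samples: after
#' scaling, any two tracks have identical genome-wide totals, so genuine
#' global differences must be restored afterwards by
#' [applyGlobalCalibration()].  Relative bin ratios are preserved.
#'
#' @param x a [SignalTrack-class] with at least one non-zero value.
#' @return The scaled track; the factor applied is recorded in
#'   `trackMeta(x)$scale`.
#' @aliases scaleToUnitMean,SignalTrack-method
#' @export
setMethod("scaleToUnitMean", "SignalTrack", function(x) {
    total <- sum(unlist(x@values, use.names = FALSE))
    if (total <= 0)
        stop("all-zero track: unit-mean scaling is undefined")
    f <- nBins(x) / total
    x@values <- lapply(x@values, function(v) v * f)
    x@meta$scale <- list(factor = f, rawMean = 1 / f)
    x@meta$unitMean <- TRUE
    validObject(x)
    x
})

#' Parameters of the Poisson input subtraction
#'
#' @param pUpper upper-tail probability of the Poisson bound (default
#'   0.001): the background estimate subtracted per bin is the smallest
#'   integer `k` with `P(Poisson(lambda) <= k) >= 1 - pUpper`.
#' @param floor minimum output value (0).
#' @return A validated parameter list.
#' @export
subtractionParams <- function(pUpper = 0.001, floor = 0) {
    stopifnot(pUpper > 0, pUpper < 1, floor >= 0)
    list(pUpper = pUpper, floor = floor)
}

#' Subtract input background from a ChIP track under a Poisson model
#'
#' Both tracks must share the bin grid and be unit-mean scaled.  The
#' input intensity of each bin is rescaled to the ChIP sample's read
#' depth to give the Poisson rate `lambda`; the background subtracted is
#' the upper `1 - pUpper` Poisson quantile of that rate (the smallest
#' integer `k` whose CDF reaches `1 - pUpper`), converted back to
#' intensity units; the result is floored at 0.  This is a conservative
#' rule: a bin survives only if its ChIP signal exceeds what background
#' alone would produce with probability `1 - pUpper`.
#'
#' @param chip,input [SignalTrack-class] objects on the same grid, in
#'   the same (typically unit-mean scaled) intensity units; `depth`
#'   converts those units to Poisson read counts.
#' @param params a [subtractionParams()] list.
#' @param depth expected ChIP reads per bin used to convert intensity to
#'   Poisson counts; defaults to `nReads(chip) / nBins(chip)`.
#' @return The background-subtracted track (values >= 0 everywhere).
#' @export
subtractInput <- function(chip, input, params = subtractionParams(),
                          depth = NULL) {
    stopifnot(is(chip, "SignalTrack"), is(input, "SignalTrack"))
    if (chip@binSize != input@binSize ||
        !identical(chip@chromSizes, input@chromSizes))
        stop("chip and input tracks are on different bin grids")
    if (sum(unlist(input@values, use.names = FALSE)) == 0) {
        warning("all-zero input track: treating background as 0 everywhere")
        chip@meta$subtract <- list(pUpper = params$pUpper, depth = NA_real_)
        return(chip)
    }
    if (is.null(depth)) {
        if (is.na(chip@nReads))
            stop("chip track has no read count: supply depth explicitly")
        depth <- chip@nReads / nBins(chip)
    }
    stopifnot(depth > 0)
    chip@values <- lapply(names(chip@values), function(ch) {
        lam <- input@values[[ch]] * depth
        u <- qpois(1 - params$pUpper, lam)
        pmax(chip@values[[ch]] - u / depth, params$floor)
    })
    names(chip@values) <- names(chip@chromSizes)
    chip@meta$subtract <- list(pUpper = params$pUpper, depth = depth)
    validObject(chip)
    chip
}

#' Restore global differences with the Western-blot factor
#'
#' Multiplies a normalized track by the sample's global modification
#' level from the calibration table.  Unit-mean scaling forces every
#' sample to the same genome-wide total, erasing true global changes
#' (e.g. a uniform depletion of a mark); multiplying by the
#' independently measured global level puts them back: the reference
#' sample (level 1) is unchanged and a depleted sample's genome-wide
#' mean becomes its global level.
#'
#' @param track a normalized [SignalTrack-class] whose `sampleId` and
#'   `mark` appear in `calib`.
#' @param calib a [CalibrationTable-class].
#' @return The calibrated track; the level applied is recorded in
#'   `trackMeta(track)$calibration`.
#' @export
applyGlobalCalibration <- function(track, calib) {
    stopifnot(is(track, "SignalTrack"), is(calib, "CalibrationTable"))
    level <- globalLevel(calib, sampleId(track), trackMark(track))
    track@values <- lapply(track@values, function(v) v * level)
    track@meta$calibration <- list(level = level)
    track
}

## Overlap-weighted mean of track bins across the 1-based closed
## interval [from, to] on one chromosome's value vector.
weightedRegionMean <- function(v, binSize, from, to) {
    b1 <- (from - 1L) %/% binSize + 1L
    b2 <- (to - 1L) %/% binSize + 1L
    idx <- b1:b2
    bin_start <- (idx - 1L) * binSize + 1L
    bin_end <- idx * binSize
    w <- pmin(to, bin_end) - pmax(from, bin_start) + 1L
    sum(v[idx] * w) / sum(w)
}

#' Mean signal over each gene body
#'
#' Per gene, the overlap-weighted mean of track bins across the gene
#' body: edge bins contribute in proportion to the bases they share with
#' the gene.
#'
#' @param track a (typically calibrated) [SignalTrack-class].
#' @param genome a [GenomeModel-class]; a gene on a chromosome absent
#'   from the track is an error.
#' @return data.frame with columns `gene_id`, `mean_signal`.
#' @export
geneBodySignal <- function(track, genome) {
    g <- genes(genome)
    chs <- as.character(seqnames(g))
    if (any(!chs %in% names(trackValues(track))))
        stop("gene on chromosome absent from the track")
    v <- trackValues(track)
    bs <- binSize(track)
    ms <- vapply(seq_along(g), function(i)
        weightedRegionMean(v[[chs[i]]], bs, start(g)[i], end(g)[i]),
        numeric(1))
    data.frame(gene_id = geneIds(genome), mean_signal = ms)
}

#' Strand-aware metagene profile around the TSS
#'
#' Splits a +/- `window` bp region around each TSS into `step`-bp
#' sub-windows and records the overlap-weighted mean track intensity in
#' each.  Rows of minus-strand genes are flipped so positive offsets are
#' always downstream in the transcription sense; offsets are sub-window
#' centres, symmetric about 0.  Genes whose window would cross a
#' chromosome boundary are dropped (their number is reported in a
#' message and stored in the object) rather than zero-padded.
#'
#' @param track a calibrated [SignalTrack-class].
#' @param genome a [GenomeModel-class].
#' @param window half-width of the profile in bases (default 2500).
#' @param step sub-window width in bases (default 50); `window` must be
#'   a multiple of `step`.
#' @param groups a [GenePartition-class] or named list of gene-id
#'   vectors; default is one group `"all"` containing every gene.  An
#'   empty group is an error.
#' @return A [ProfileMatrix-class]; per-group mean curves via
#'   [groupCurves()].
#' @export
tssProfile <- function(track, genome, window = 2500L, step = 50L,
                       groups = NULL) {
    stopifnot(window > 0L, step > 0L)
    if (window %% step != 0L)
        stop("window must be a multiple of step")
    if (is.null(groups))
        groups <- list(all = geneIds(genome))
    if (is(groups, "GenePartition"))
        groups <- partitionSets(groups)
    for (nm in names(groups))
        if (length(groups[[nm]]) == 0L)
            stop("empty gene group: '", nm, "'")
    ids <- unique(unlist(groups, use.names = FALSE))
    g <- genes(genome)
    keep <- geneIds(genome) %in% ids
    g <- g[keep]
    gids <- geneIds(genome)[keep]
    if (!all(ids %in% gids))
        stop("group gene(s) absent from the genome annotation")
    cs <- chromSizes(genome)
    tss <- ifelse(as.character(strand(g)) == "+", start(g), end(g))
    L <- cs[as.character(seqnames(g))]
    ok <- tss - window >= 1L & tss + window <= L
    ndrop <- sum(!ok)
    if (ndrop > 0L)
        message("dropping ", ndrop, " gene(s) whose TSS window exceeds chromosome bounds")
    g <- g[ok]; gids <- gids[ok]; tss <- tss[ok]
    ncols <- as.integer(2L * window / step)
    offsets <- -window + step / 2 + (seq_len(ncols) - 1L) * step
    v <- trackValues(track)
    bs <- binSize(track)
    mat <- matrix(NA_real_, nrow = length(g), ncol = ncols,
                  dimnames = list(gids, offsets))
    minus <- as.character(strand(g)) == "-"
    for (i in seq_along(g)) {
        ch <- as.character(seqnames(g))[i]
        for (j in seq_len(ncols)) {
            o <- offsets[j]
            if (!minus[i]) {
                from <- tss[i] + o - step / 2
                to <- from + step - 1L
            } else {
                to <- tss[i] - o + step / 2
                from <- to - step + 1L
            }
            mat[i, j] <- weightedRegionMean(v[[ch]], bs, as.integer(from),
                                            as.integer(to))
        }
    }
    groups <- lapply(groups, function(x) intersect(x, gids))
    for (nm in names(groups))
        if (length(groups[[nm]]) == 0L)
            stop("group '", nm, "' lost all genes to boundary dropping")
    new("ProfileMatrix", offsets = as.numeric(offsets), mat = mat,
        groups = groups, dropped = as.integer(ndrop))
}

#' Pointwise ratio of two metagene curves
#'
#' Computes `me2 / (me3 + eps)` offset by offset, e.g. the
#' H3K36me2/H3K27me3 ratio around the TSS.  The guard `eps` keeps the
#' ratio finite where the denominator reaches 0 and is disclosed in the
#' result's attributes.
#'
#' @param me2,me3 numeric vectors (or matrices of group curves from
#'   [groupCurves()]) sharing offset names; mismatched offsets are an
#'   error.
#' @param eps denominator guard, in the same intensity units as `me3`
#'   (default 0.01, i.e. 1% of a unit-mean genome average).
#' @return Ratio curve(s) with attribute `eps`.
#' @export
ratioProfile <- function(me2, me3, eps = 0.01) {
    nm2 <- if (is.matrix(me2)) colnames(me2) else names(me2)
    nm3 <- if (is.matrix(me3)) colnames(me3) else names(me3)
    if (!identical(nm2, nm3) || is.null(nm2))
        stop("curves must share identical offsets")
    stopifnot(eps >= 0)
    out <- me2 / (me3 + eps)
    attr(out, "eps") <- eps
    out
}

#' Aggregate a fine-binned track to a coarser grid
#'
#' Merges each run of `factor` consecutive bins into one; the new value
#' is the total base overlap divided by the new bin size, so aggregating
#' a per-nucleotide track by `k` reproduces direct computation at
#' `binSize = k` exactly.
#'
#' @param track a [SignalTrack-class].
#' @param factor integer number of bins to merge.
#' @return A [SignalTrack-class] with `binSize * factor`.
#' @export
rebinTrack <- function(track, factor) {
    factor <- as.integer(factor)
    stopifnot(factor >= 1L)
    vals <- lapply(track@values, function(v) {
        grp <- (seq_along(v) - 1L) %/% factor
        as.numeric(tapply(v, grp, sum)) / factor
    })
    SignalTrack(vals, track@binSize * factor, track@chromSizes,
                sampleId = track@sampleId, mark = track@mark,
                condition = track@condition, nReads = track@nReads,
                meta = track@meta)
}
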