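#' @importFrom stats rpois rnorm runif rlnorm qpois ppois dpois setNames
#' @importFrom withr with_seed
NULL

## Deterministic substream seed for a labelled stream. Each (purpose,
## sample) label gets its own stream so adding a sample never perturbs
## another sample's draws. Result stays within 32-bit integer range.
streamSeed <- function(seed, label) {
    h <- 0
    for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 2147480009
    as.integer((as.numeric(seed) * 48271 + h) %% 2147480009)
}

#' Generate a toy genome with non-overlapping genes
#'
#' Places `nGenes` genes round-robin across `nChroms` chromosomes of
#' `chromLength` bases.  Each chromosome is divided into equal slots and
#' one gene is placed at a random offset inside each slot, guaranteeing
#' non-overlap; a margin is kept at slot edges so default TSS windows
#' stay inside chromosome bounds.  Strands are drawn at random (both
#' strands represented for two or more genes), and each gene gets an
#' exonic length of 50-90% of its span, realized as a two-exon model
#' (one exon anchored at each gene end) when written as BED12.
#'
#' @param spec a [SyntheticSpec-class].
#' @return A [GenomeModel-class]; deterministic for a fixed
#'   `spec@seed`.
#' @export
makeGenome <- function(spec) {
    stopifnot(is(spec, "SyntheticSpec"))
    validObject(spec)
    cs <- setNames(rep(spec@chromLength, spec@nChroms),
                   paste0("chr", seq_len(spec@nChroms)))
    if (spec@nGenes == 0L)
        return(GenomeModel(cs, GRanges()))
    chrom_of <- rep(names(cs), length.out = spec@nGenes)
    with_seed(streamSeed(spec@seed, "genome"), {
        recs <- lapply(names(cs), function(ch) {
            idx <- which(chrom_of == ch)
            k <- length(idx)
            if (k == 0L) return(NULL)
            slot <- floor(spec@chromLength / k)
            margin <- min(2600L, floor(slot / 8))
            maxlen <- slot - 2L * margin
            if (maxlen < spec@binSize)
                stop("cannot place ", k, " non-overlapping genes on a ",
                     spec@chromLength, " bp chromosome")
            len <- pmin(maxlen, round(runif(k, 2000, 8000)))
            len <- pmax(len, spec@binSize)
            off <- floor(runif(k, 0, maxlen - len + 1))
            start <- (seq_len(k) - 1L) * slot + margin + off + 1L
            data.frame(chrom = ch, start = start, end = start + len - 1L,
                       idx = idx)
        })
        recs <- do.call(rbind, recs)
        recs <- recs[order(recs$idx), ]
        strand <- sample(c("+", "-"), spec@nGenes, replace = TRUE)
        if (spec@nGenes >= 2L && length(unique(strand)) == 1L)
            strand[1L] <- setdiff(c("+", "-"), strand[1L])
        exo_frac <- runif(spec@nGenes, 0.5, 0.9)
    })
    width <- recs$end - recs$start + 1L
    g <- GRanges(recs$chrom, IRanges(recs$start, recs$end), strand = strand)
    S4Vectors::mcols(g)$gene_id <- sprintf("g%04d", seq_len(spec@nGenes))
    S4Vectors::mcols(g)$exonic_length <- pmax(2L, as.integer(round(width * exo_frac)))
    GenomeModel(cs, g)
}

## Genes carrying planted enrichment domains: a seeded shuffle of all
## genes, split into consecutive blocks, one block per domain. The same
## stream is used for every condition so control and mutant share domains.
enrichedGeneSets <- function(genome, spec, mark) {
    ids <- geneIds(genome)
    if (is.null(ids) || length(ids) == 0L || !length(spec@enrichmentDomains))
        return(list())
    perm <- with_seed(streamSeed(spec@seed, paste0("domains:", mark)),
                      sample(ids))
    out <- list()
    cursor <- 0L
    for (i in seq_along(spec@enrichmentDomains)) {
        d <- spec@enrichmentDomains[[i]]
        n <- round(d[1] * length(ids))
        take <- perm[seq_len(min(n, length(perm) - cursor)) + cursor]
        cursor <- cursor + length(take)
        out[[i]] <- list(genes = take, fold = d[2])
    }
    out
}

## Per-chromosome Poisson rate vectors (expected reads per bin).
chipRates <- function(genome, spec, domains, where = c("body", "tss")) {
    where <- match.arg(where)
    cs <- chromSizes(genome)
    g <- genes(genome)
    ids <- geneIds(genome)
    rates <- lapply(names(cs), function(ch) {
        rep(spec@backgroundRate, ceiling(cs[[ch]] / spec@binSize))
    })
    names(rates) <- names(cs)
    half <- 500L  # half-width of the triangular TSS plant
    for (dom in domains) {
        sel <- g[ids %in% dom$genes]
        if (where == "tss") {
            ## triangular kernel peaking in the TSS bin so profile
            ## localization is testable against a true maximum at 0
            tss <- ifelse(as.character(strand(sel)) == "+", start(sel), end(sel))
            for (i in seq_along(sel)) {
                ch <- as.character(seqnames(sel))[i]
                b1 <- max(1L, (tss[i] - half - 1L) %/% spec@binSize + 1L)
                b2 <- min(length(rates[[ch]]),
                          (tss[i] + half - 1L) %/% spec@binSize + 1L)
                centre <- ((b1:b2) - 0.5) * spec@binSize
                w <- pmax(0, 1 - abs(centre - tss[i]) / half)
                rates[[ch]][b1:b2] <- rates[[ch]][b1:b2] *
                    (1 + (dom$fold - 1) * w)
            }
        } else {
            for (i in seq_along(sel)) {
                ch <- as.character(seqnames(sel))[i]
                b1 <- (start(sel)[i] - 1L) %/% spec@binSize + 1L
                b2 <- (end(sel)[i] - 1L) %/% spec@binSize + 1L
                rates[[ch]][b1:b2] <- rates[[ch]][b1:b2] * dom$fold
            }
        }
    }
    rates
}

## Draw reads bin by bin from per-bin Poisson rates.
drawReads <- function(rates, chromSizes, binSize, readLength) {
    per_chrom <- lapply(names(rates), function(ch) {
        counts <- rpois(length(rates[[ch]]), rates[[ch]])
        tot <- sum(counts)
        if (tot == 0L)
            return(GRanges())
        bin_idx <- rep.int(seq_along(counts), counts)
        starts <- (bin_idx - 1L) * binSize +
            floor(runif(tot, 0, binSize)) + 1L
        ends <- pmin(starts + readLength - 1L, chromSizes[[ch]])
        GRanges(ch, IRanges(starts, ends))
    })
    out <- suppressWarnings(do.call(c, per_chrom))
    GenomeInfoDb::seqlevels(out) <- names(chromSizes)
    GenomeInfoDb::seqlengths(out) <- unname(chromSizes)
    out
}

#' Simulate ChIP reads with planted enrichment and global depletion
#'
#' Per-bin read counts are Poisson with rate `backgroundRate`, multiplied
#' by each enrichment domain's fold over its planted genes: uniformly
#' over gene bodies (default), or as a triangular bump of 500 bp
#' half-width peaking in the TSS bin with `enrichAt = "tss"`.  For the mutant
#' condition the whole rate field is multiplied by
#' `spec@globalDepletion`, emulating a uniform global loss of the mark.
#' The true factor and true enriched gene sets are returned alongside the
#' reads so downstream recovery can be checked against ground truth.
#'
#' @param genome a [GenomeModel-class] from [makeGenome()].
#' @param spec the [SyntheticSpec-class] used to build `genome`.
#' @param mark histone-mark label, e.g. `"H3K36me2"`.
#' @param condition `"CTRL"` or `"MUT"`; depletion applies to `"MUT"`.
#' @param enrichAt plant enrichment on gene bodies (default) or around
#'   the TSS.
#' @return list with elements `reads` (a `GRanges` of read intervals) and
#'   `truth` (list: `globalFactor`, `enrichedGenes` per domain, `mark`,
#'   `condition`, `nReads`).
#' @export
simulateChipReads <- function(genome, spec, mark = "H3K36me2",
                              condition = c("CTRL", "MUT"),
                              enrichAt = c("body", "tss")) {
    condition <- match.arg(condition)
    enrichAt <- match.arg(enrichAt)
    domains <- enrichedGeneSets(genome, spec, mark)
    rates <- chipRates(genome, spec, domains, enrichAt)
    g <- if (condition == "MUT") spec@globalDepletion else 1
    rates <- lapply(rates, function(r) r * g)
    reads <- with_seed(streamSeed(spec@seed, paste("chip", mark, condition)),
                       drawReads(rates, chromSizes(genome), spec@binSize,
                                 spec@readLength))
    list(reads = reads,
         truth = list(globalFactor = g,
                      enrichedGenes = lapply(domains, `[[`, "genes"),
                      mark = mark, condition = condition,
                      nReads = length(reads)))
}

#' Simulate a sequencing input control
#'
#' Uniform Poisson background at `spec@backgroundRate` reads per bin on
#' every chromosome; no enrichment and no condition effect.
#'
#' @param genome a [GenomeModel-class].
#' @param spec the matching [SyntheticSpec-class].
#' @param sampleId label; also keys the random substream, so distinct
#'   input samples are independent.
#' @return A `GRanges` of read intervals.
#' @export
simulateInputReads <- function(genome, spec, sampleId = "input") {
    cs <- chromSizes(genome)
    rates <- lapply(names(cs), function(ch)
        rep(spec@backgroundRate, ceiling(cs[[ch]] / spec@binSize)))
    names(rates) <- names(cs)
    with_seed(streamSeed(spec@seed, paste("input", sampleId)),
              drawReads(rates, cs, spec@binSize, spec@readLength))
}

#' Simulate a four-sample expression table with planted truth
#'
#' Generates samples WT_D0, WT_D2, MUT_D0 and MUT_D2.  A seeded shuffle
#' picks `round(inducedFraction * nGenes)` induced genes whose true
#' D0 to D2 fold in the control is `inducedFold`; of these,
#' `round(sensitiveFraction * nInduced)` are sensitive (mutant fold 1,
#' i.e. they fail to be induced in the mutant) and the rest are resistant
#' (mutant fold equals the control fold).  Baseline abundances are
#' log-normal around 10 RPKM; with `noiseSd > 0` every expected value is
#' multiplied by an independent log-normal factor before being converted
#' to integer counts at a fixed library size of one million reads.
#'
#' @param genome a [GenomeModel-class] with at least one gene.
#' @param spec the matching [SyntheticSpec-class]; `spec@noiseSd = 0`
#'   gives the noiseless mode in which classification recovers the truth
#'   exactly.
#' @return list with `expr` (an [ExpressionTable-class]) and `truth` (a
#'   [GenePartition-class] with sets `sensitive`, `resistant` and
#'   `uninduced`; the planted induced set is `sensitive` + `resistant`).
#' @export
simulateExpression <- function(genome, spec) {
    ids <- geneIds(genome)
    n <- length(ids)
    if (n == 0L) stop("genome has no genes")
    nInd <- round(spec@inducedFraction * n)
    if (spec@inducedFraction > 0 && nInd == 0L)
        warning("inducedFraction * nGenes < 1: zero genes planted as induced")
    nSens <- round(spec@sensitiveFraction * nInd)
    if (nInd > 0L && spec@sensitiveFraction > 0 && nSens == 0L)
        warning("sensitiveFraction * nInduced < 1: zero genes planted as sensitive")
    samples <- c("WT_D0", "WT_D2", "MUT_D0", "MUT_D2")
    lib <- 1e6
    lens <- S4Vectors::mcols(genes(genome))$exonic_length
    with_seed(streamSeed(spec@seed, "expression"), {
        perm <- sample(ids)
        base <- rlnorm(n, meanlog = log(10), sdlog = 0.5)
        noise <- if (spec@noiseSd > 0)
            matrix(exp(rnorm(n * 4L, 0, spec@noiseSd)), n, 4L)
        else matrix(1, n, 4L)
    })
    sens <- perm[seq_len(nSens)]
    resist <- perm[seq_len(nInd - nSens) + nSens]
    induced <- c(sens, resist)
    fold_wt <- ifelse(ids %in% induced, spec@inducedFold, 1)
    fold_mut <- ifelse(ids %in% resist, spec@inducedFold, 1)
    mean_mat <- cbind(WT_D0 = base, WT_D2 = base * fold_wt,
                      MUT_D0 = base, MUT_D2 = base * fold_mut)
    counts <- round(mean_mat * noise * (lens / 1000) * (lib / 1e6))
    dimnames(counts) <- list(ids, samples)
    expr <- ExpressionTable(counts, exonicLength = lens,
                            librarySize = setNames(rep(lib, 4L), samples))
    truth <- GenePartition("planted",
                           list(sensitive = sens, resistant = resist,
                                uninduced = setdiff(ids, induced)),
                           params = list(inducedFold = spec@inducedFold,
                                         noiseSd = spec@noiseSd))
    list(expr = expr, truth = truth)
}

#' Write a complete synthetic workspace to disk
#'
#' Generates the toy genome, ChIP and input reads for two marks and two
#' conditions, the expression table, the ground-truth sidecar and a
#' calibration table whose mutant rows carry the planted global
#' depletion, then writes everything in standard plain-text formats:
#' BED12 annotation, 6-column BED reads, TSV tables, YAML spec.
#'
#' @param spec a [SyntheticSpec-class].
#' @param dir output directory (created if needed).
#' @param marks histone-mark labels to simulate.
#' @return Invisibly, a list of file paths plus the in-memory `truth`
#'   records.
#' @export
writeSyntheticWorkspace <- function(spec, dir,
                                    marks = c("H3K36me2", "H3K27me3")) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    genome <- makeGenome(spec)
    paths <- list(annotation = file.path(dir, "genes.bed"),
                  chromSizes = file.path(dir, "chrom.sizes"),
                  expression = file.path(dir, "expression.tsv"),
                  truth = file.path(dir, "truth.tsv"),
                  calibration = file.path(dir, "calibration.tsv"),
                  spec = file.path(dir, "spec.yaml"))
    writeAnnotation(genome, paths$annotation)
    writeChromSizes(chromSizes(genome), paths$chromSizes)
    sim <- simulateExpression(genome, spec)
    writeExpression(sim$expr, paths$expression)
    writePartition(sim$truth, paths$truth)
    truth <- list(expression = sim$truth)
    calib <- NULL
    reads <- list()
    for (mk in marks) {
        for (cond in c("CTRL", "MUT")) {
            sid <- paste(cond, mk, sep = "_")
            cr <- simulateChipReads(genome, spec, mark = mk, condition = cond)
            p <- file.path(dir, paste0("chip_", sid, ".bed"))
            writeReads(cr$reads, p)
            reads[[sid]] <- p
            truth[[sid]] <- cr$truth
            calib <- rbind(calib,
                           data.frame(sample_id = sid, mark = mk,
                                      global_level = cr$truth$globalFactor))
        }
    }
    inp <- simulateInputReads(genome, spec, sampleId = "input")
    paths$input <- file.path(dir, "input.bed")
    writeReads(inp, paths$input)
    writeCalibration(CalibrationTable(calib), paths$calibration)
    yaml::write_yaml(specAsList(spec), paths$spec)
    invisible(c(paths, list(chipReads = reads, truth = truth,
                            genome = genome)))
}

specAsList <- function(spec) {
    list(nChroms = spec@nChroms, chromLength = spec@chromLength,
         nGenes = spec@nGenes, binSize = spec@binSize,
         enrichmentDomains = lapply(spec@enrichmentDomains, as.numeric),
         globalDepletion = spec@globalDepletion,
         backgroundRate = spec@backgroundRate,
         inducedFraction = spec@inducedFraction,
         sensitiveFraction = spec@sensitiveFraction,
         inducedFold = spec@inducedFold, noiseSd = spec@noiseSd,
         readLength = spec@readLength, seed = spec@seed)
}
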