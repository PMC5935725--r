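#' @importFrom tools md5sum
#' @importFrom grDevices pdf dev.off hcl.colors
#' @importFrom graphics barplot image axis legend lines plot abline par
NULL

runStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

configDefaults <- list(binSize = 200L, pUpper = 0.001, threshold = 2,
                       pseudocount = 0.5, window = 2500L, step = 50L,
                       topN = 1000L)

#' Read and validate a pipeline run configuration
#'
#' The YAML config names the input files and every tunable parameter of
#' a run.  Unknown keys (at the top level and inside `params`) are
#' errors, so a typo in a threshold name cannot silently fall back to a
#' default.  Omitted parameters take the documented defaults.  The
#' validated config round-trips through YAML losslessly.
#'
#' Recognized top-level keys: `outputDir`, `seed`, `annotation`,
#' `chromSizes`, `calibration`, `input`, `chip` (list of entries with
#' `sample`, `mark`, `condition`, `reads`), `counts`, `samples` (labels
#' `controlFrom`, `controlTo`, `mutantFrom`, `mutantTo`, `selectivityA`,
#' `selectivityB`), `groups` (partition TSV for TSS profiles), `params`
#' (`binSize`, `pUpper`, `threshold`, `pseudocount`, `window`, `step`,
#' `topN`).
#'
#' @param path YAML file.
#' @return A validated config list (class `"RunConfig"`).
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    allowed <- c("outputDir", "seed", "annotation", "chromSizes",
                 "calibration", "input", "chip", "counts", "samples",
                 "groups", "params")
    extra <- setdiff(names(cfg), allowed)
    if (length(extra))
        stop("unknown config key(s): ", paste(extra, collapse = ", "))
    if (is.null(cfg$outputDir)) stop("config requires outputDir")
    p <- cfg$params
    if (!is.null(p)) {
        bad <- setdiff(names(p), names(configDefaults))
        if (length(bad))
            stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    }
    cfg$params <- modifyList(configDefaults, if (is.null(p)) list() else p)
    p <- cfg$params
    stopifnot(p$binSize >= 1, p$pUpper > 0, p$pUpper < 1,
              p$threshold > 1, p$pseudocount >= 0, p$window > 0,
              p$step > 0, p$window %% p$step == 0, p$topN >= 1)
    structure(cfg, class = "RunConfig")
}

#' Run the quantitative ChIP normalization pipeline
#'
#' For every configured ChIP sample: binned coverage, unit-mean scaling,
#' Poisson input subtraction against the shared input, Western-blot
#' global calibration, then a calibrated bedGraph, a per-gene body-mean
#' table, and (when a gene-group file is configured) TSS metagene
#' curves.  A manifest records every numeric factor applied per sample
#' (scaling factor, subtraction depth and tail probability, calibration
#' level) plus md5 checksums of every output, so a rerun can be checked
#' for bit-identity.  Any stage error aborts naming the stage.
#'
#' @param config a `RunConfig` from [readRunConfig()].
#' @return Invisibly, a list with the calibrated tracks, the gene-body
#'   table, profile curves (if any) and the manifest.
#' @export
runChipPipeline <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    p <- config$params
    out <- config$outputDir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    genome <- runStage("annotation", {
        cs <- if (!is.null(config$chromSizes))
            readChromSizes(config$chromSizes) else NULL
        readAnnotation(config$annotation, chromSizes = cs)
    })
    calib <- runStage("calibration", {
        if (is.null(config$calibration))
            stop("no calibration file configured")
        readCalibration(config$calibration)
    })
    input_scaled <- runStage("input", {
        reads <- readReads(config$input, chromSizes(genome))
        scaleToUnitMean(computeCoverage(reads, genome, p$binSize,
                                        sampleId = "input"))
    })
    groups <- if (!is.null(config$groups))
        runStage("groups", readPartition(config$groups)) else NULL
    manifest <- list(params = p, samples = list())
    tracks <- list()
    body_tab <- NULL
    curves <- list()
    for (entry in config$chip) {
        sid <- entry$sample
        tr <- runStage(paste0("coverage:", sid), {
            reads <- readReads(entry$reads, chromSizes(genome))
            computeCoverage(reads, genome, p$binSize, sampleId = sid,
                            mark = entry$mark, condition = entry$condition)
        })
        tr <- runStage(paste0("scale:", sid), scaleToUnitMean(tr))
        tr <- runStage(paste0("subtract:", sid),
                       subtractInput(tr, input_scaled,
                                     subtractionParams(pUpper = p$pUpper)))
        tr <- runStage(paste0("calibrate:", sid),
                       applyGlobalCalibration(tr, calib))
        writeTrack(tr, file.path(out, paste0(sid, ".bedGraph")))
        tracks[[sid]] <- tr
        gb <- runStage(paste0("genebody:", sid), geneBodySignal(tr, genome))
        colnames(gb)[2] <- sid
        body_tab <- if (is.null(body_tab)) gb else merge(body_tab, gb, by = "gene_id")
        if (!is.null(groups)) {
            pm <- runStage(paste0("tssprofile:", sid),
                           tssProfile(tr, genome, p$window, p$step, groups))
            curves[[sid]] <- groupCurves(pm)
            cv <- data.frame(offset = profileOffsets(pm),
                             t(curves[[sid]]), check.names = FALSE)
            write.table(cv, file.path(out, paste0(sid, "_tss.tsv")),
                        sep = "\t", quote = FALSE, row.names = FALSE)
        }
        m <- trackMeta(tr)
        manifest$samples[[sid]] <-
            list(nReads = m$coverage$nReads,
                 scaleFactor = m$scale$factor,
                 subtractPUpper = m$subtract$pUpper,
                 subtractDepth = m$subtract$depth,
                 calibrationLevel = m$calibration$level)
    }
    write.table(body_tab, file.path(out, "gene_body_signal.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    files <- list.files(out, pattern = "\\.(bedGraph|tsv)$",
                        full.names = TRUE)
    manifest$md5 <- as.list(md5sum(files))
    names(manifest$md5) <- basename(files)
    yaml::write_yaml(manifest, file.path(out, "chip_manifest.yaml"))
    invisible(list(tracks = tracks, geneBody = body_tab, curves = curves,
                   manifest = manifest, genome = genome))
}

#' Run the expression classification pipeline
#'
#' RPKM, twofold regulation calls on the control pair,
#' sensitive/resistant partition of the control-up genes against the
#' mutant pair, selectivity ranking and the log2 fold-change heatmap
#' matrix, plus a summary report with set sizes and percentages.
#'
#' @param config a `RunConfig` from [readRunConfig()]; requires `counts`
#'   and the `samples` labels.
#' @return Invisibly, a list with the partitions, ranking, heatmap
#'   matrix, summary and manifest.
#' @export
runExpressionPipeline <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    p <- config$params
    s <- config$samples
    out <- config$outputDir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    expr <- runStage("counts", {
        if (is.null(config$counts)) stop("no counts table configured")
        computeRPKM(readExpression(config$counts))
    })
    reg <- runStage("classify",
                    callRegulated(expr, s$controlFrom, s$controlTo,
                                  p$threshold, p$pseudocount))
    writePartition(reg, file.path(out, "regulation.tsv"))
    sens <- runStage("sensitivity",
                     partitionSensitivity(reg, expr, s$mutantFrom,
                                          s$mutantTo, p$threshold,
                                          p$pseudocount))
    writePartition(sens, file.path(out, "sensitivity.tsv"))
    sens_level <- runStage("sensitivity",
                           partitionSensitivity(reg, expr, s$mutantFrom,
                                                s$mutantTo, p$threshold,
                                                p$pseudocount,
                                                rule = "level",
                                                controlTo = s$controlTo))
    ov <- runStage("overlap",
                   overlapSets(partitionSets(sens)$sensitive,
                               partitionSets(sens_level)$sensitive))
    write.table(data.frame(set = names(ov$counts), n = ov$counts),
                file.path(out, "overlap_counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ranking <- runStage("rankselect",
                        rankSelectivity(expr, s$selectivityA,
                                        s$selectivityB, p$topN,
                                        p$pseudocount))
    write.table(rankingTable(ranking), file.path(out, "selectivity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    hm <- runStage("heatmap",
                   heatmapMatrix(expr,
                                 contrasts = list(
                                     c(s$selectivityA, s$selectivityB),
                                     c(s$mutantTo, s$controlTo)),
                                 ranking = ranking,
                                 pseudocount = p$pseudocount))
    write.table(data.frame(gene_id = rownames(hm), hm,
                           check.names = FALSE),
                file.path(out, "heatmap_matrix.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    fr <- summarizeFractions(reg, nrow(expr))
    summary <- list(nGenes = nrow(expr),
                    counts = as.list(lengths(partitionSets(reg))),
                    percent = as.list(fr),
                    sensitive = length(partitionSets(sens)$sensitive),
                    resistant = length(partitionSets(sens)$resistant),
                    overlapFoldVsLevel = as.list(ov$counts))
    yaml::write_yaml(summary, file.path(out, "expression_summary.yaml"))
    files <- list.files(out, pattern = "\\.tsv$", full.names = TRUE)
    manifest <- list(params = p, samples = s,
                     md5 = as.list(md5sum(files)))
    names(manifest$md5) <- basename(files)
    yaml::write_yaml(manifest, file.path(out, "expression_manifest.yaml"))
    invisible(list(regulation = reg, sensitivity = sens,
                   sensitivityLevelRule = sens_level, overlap = ov,
                   ranking = ranking, heatmap = hm, summary = summary,
                   manifest = manifest))
}

## Config list for a synthetic workspace written by writeSyntheticWorkspace.
demoConfig <- function(ws_dir, out_dir, seed,
                       marks = c("H3K36me2", "H3K27me3"), topN = 10L) {
    chip <- list()
    for (mk in marks)
        for (cond in c("CTRL", "MUT"))
            chip[[length(chip) + 1L]] <-
                list(sample = paste(cond, mk, sep = "_"), mark = mk,
                     condition = cond,
                     reads = file.path(ws_dir, sprintf("chip_%s_%s.bed",
                                                       cond, mk)))
    list(outputDir = out_dir, seed = seed,
         annotation = file.path(ws_dir, "genes.bed"),
         chromSizes = file.path(ws_dir, "chrom.sizes"),
         calibration = file.path(ws_dir, "calibration.tsv"),
         input = file.path(ws_dir, "input.bed"),
         chip = chip,
         counts = file.path(ws_dir, "expression.tsv"),
         groups = file.path(ws_dir, "truth.tsv"),
         samples = list(controlFrom = "WT_D0", controlTo = "WT_D2",
                        mutantFrom = "MUT_D0", mutantTo = "MUT_D2",
                        selectivityA = "WT_D2", selectivityB = "MUT_D2"),
         params = modifyList(configDefaults, list(topN = topN)))
}

#' Build and analyse a self-contained demo workspace
#'
#' Generates a synthetic dataset with planted ground truth, writes it to
#' disk in standard formats, runs the full ChIP and expression pipelines
#' on the files, and (optionally) draws summary figures: classification
#' counts, the overlap between the two sensitivity rules, the
#' selectivity heatmap and the TSS H3K36me2/H3K27me3 ratio curves for
#' control versus mutant.
#'
#' @param seed integer seed driving all randomness.
#' @param dir workspace directory (default: fresh temporary directory).
#' @param figures draw PDF figures under `dir/figures` (default TRUE).
#'   Data outputs are identical either way; figure files embed a
#'   creation timestamp and are therefore excluded from the hash
#'   manifest.
#' @return Invisibly, a list with the workspace paths, both pipeline
#'   results and `hashes` (md5 of every data output).
#' @export
makeDemo <- function(seed = 1L, dir = tempfile("chipcalib_demo"),
                     figures = TRUE) {
    spec <- syntheticSpec(seed = seed)
    ws_dir <- file.path(dir, "data")
    out_dir <- file.path(dir, "results")
    ws <- writeSyntheticWorkspace(spec, ws_dir)
    cfg_path <- file.path(dir, "config.yaml")
    yaml::write_yaml(demoConfig(ws_dir, out_dir, seed), cfg_path)
    config <- readRunConfig(cfg_path)
    chip <- suppressMessages(runChipPipeline(config))
    exprres <- runExpressionPipeline(config)
    files <- sort(c(list.files(ws_dir, full.names = TRUE),
                    list.files(out_dir, full.names = TRUE)))
    hashes <- md5sum(files)
    names(hashes) <- sub(paste0("^", dir, "/?"), "", files)
    write.table(data.frame(file = names(hashes), md5 = unname(hashes)),
                file.path(dir, "hashes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (figures) {
        fig_dir <- file.path(dir, "figures")
        dir.create(fig_dir, showWarnings = FALSE)
        demoFigures(chip, exprres, fig_dir)
    }
    invisible(list(dir = dir, workspace = ws, chip = chip,
                   expression = exprres, hashes = hashes))
}

demoFigures <- function(chip, exprres, fig_dir) {
    pdf(file.path(fig_dir, "classification_counts.pdf"), width = 5,
        height = 4)
    cnt <- lengths(partitionSets(exprres$regulation))
    sens <- lengths(partitionSets(exprres$sensitivity))
    barplot(c(cnt, sens), col = c("firebrick", "steelblue", "grey",
                                  "darkorange", "seagreen"),
            ylab = "genes", las = 2,
            main = "Twofold regulation and mutant sensitivity")
    dev.off()
    pdf(file.path(fig_dir, "sensitivity_rule_overlap.pdf"), width = 5,
        height = 4)
    barplot(exprres$overlap$counts, col = "slategrey", ylab = "genes",
            main = "Sensitive genes: fold rule vs level rule")
    dev.off()
    pdf(file.path(fig_dir, "selectivity_heatmap.pdf"), width = 4,
        height = 6)
    hm <- exprres$heatmap
    image(t(hm[rev(seq_len(nrow(hm))), , drop = FALSE]),
          col = hcl.colors(51, "RdBu", rev = TRUE), axes = FALSE,
          main = "log2 fold change")
    axis(1, at = seq(0, 1, length.out = ncol(hm)), labels = colnames(hm),
         las = 2, cex.axis = 0.6)
    dev.off()
    if (length(chip$curves) >= 4L) {
        pdf(file.path(fig_dir, "tss_ratio.pdf"), width = 5, height = 4)
        for (cond in c("CTRL", "MUT")) {
            me2 <- chip$curves[[paste0(cond, "_H3K36me2")]]
            me3 <- chip$curves[[paste0(cond, "_H3K27me3")]]
            rows <- intersect(rownames(me2), rownames(me3))
            r <- ratioProfile(me2[rows, , drop = FALSE],
                              me3[rows, , drop = FALSE])
            off <- as.numeric(colnames(me2))
            if (cond == "CTRL")
                plot(off, r[1, ], type = "l", col = "black",
                     xlab = "distance from TSS (bp)",
                     ylab = "H3K36me2 / H3K27me3",
                     ylim = c(0, max(r) * 1.1),
                     main = "TSS ratio, control vs mutant")
            else lines(off, r[1, ], col = "firebrick")
        }
        legend("topright", legend = c("CTRL", "MUT"),
               col = c("black", "firebrick"), lty = 1, bty = "n")
        dev.off()
    }
}
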