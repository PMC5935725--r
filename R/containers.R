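#' Construct a SyntheticSpec
#'
#' Defaults are the package's reference study conditions: a 2 x 1 Mb toy
#' genome in 200 bp bins (10,000 bins), Poisson background of 5 reads per
#' bin, a 4-fold enrichment domain on the bodies of 10% of genes, a
#' global mutant depletion factor of 0.3, and an expression program with
#' 100 genes of which 20% are 4-fold induced and half of those are
#' mutant-sensitive.
#'
#' @param nChroms,chromLength,nGenes,binSize genome geometry (bases).
#' @param enrichmentDomains list of `c(fraction, fold)` enrichment
#'   domains planted on gene bodies.
#' @param globalDepletion factor in (0, 1] applied uniformly to the
#'   mutant condition's expected ChIP rate.
#' @param backgroundRate expected reads per bin outside enriched domains.
#' @param inducedFraction,sensitiveFraction,inducedFold planted
#'   expression program (see [simulateExpression()]).
#' @param noiseSd log-normal noise sd on expression means; 0 = noiseless.
#' @param readLength simulated read length (bases).
#' @param seed integer master seed.
#' @return A [SyntheticSpec-class] object.
#' @examples
#' spec <- syntheticSpec(seed = 1)
#' gm <- makeGenome(spec)
#' @export
syntheticSpec <- function(nChroms = 2L, chromLength = 1000000L, nGenes = 100L,
                          binSize = 200L,
                          enrichmentDomains = list(c(0.1, 4)),
                          globalDepletion = 0.3, backgroundRate = 5,
                          inducedFraction = 0.2, sensitiveFraction = 0.5,
                          inducedFold = 4, noiseSd = 0.1,
                          readLength = 50L, seed = 1L) {
    new("SyntheticSpec",
        nChroms = as.integer(nChroms), chromLength = as.integer(chromLength),
        nGenes = as.integer(nGenes), binSize = as.integer(binSize),
        enrichmentDomains = enrichmentDomains,
        globalDepletion = globalDepletion, backgroundRate = backgroundRate,
        inducedFraction = inducedFraction,
        sensitiveFraction = sensitiveFraction, inducedFold = inducedFold,
        noiseSd = noiseSd, readLength = as.integer(readLength),
        seed = as.integer(seed))
}

#' Construct a GenomeModel
#'
#' @param chromSizes named vector of chromosome lengths (bases).
#' @param genes `GRanges` of gene bodies with metadata columns `gene_id`
#'   and `exonic_length`; strand must be `+` or `-`.
#' @return A [GenomeModel-class] object.
#' @export
GenomeModel <- function(chromSizes, genes = GRanges()) {
    cs <- as.integer(chromSizes)
    names(cs) <- names(chromSizes)
    new("GenomeModel", chromSizes = cs, genes = genes)
}

#' @describeIn GenomeModel chromosome lengths.
#' @param x a `GenomeModel`.
#' @export
setMethod("chromSizes", "GenomeModel", function(x) x@chromSizes)

#' @describeIn GenomeModel gene annotation as `GRanges`.
#' @param ... unused.
#' @export
setMethod("genes", "GenomeModel", function(x, ...) x@genes)

#' @describeIn GenomeModel gene identifiers.
#' @export
setMethod("geneIds", "GenomeModel", function(x) S4Vectors::mcols(x@genes)$gene_id)

#' TSS positions of a genome's genes
#'
#' The transcription start site is `start` for + strand genes and `end`
#' for - strand genes (1-based coordinates).
#'
#' @param x a `GenomeModel`.
#' @return named integer vector of TSS positions.
#' @export
tssPositions <- function(x) {
    g <- genes(x)
    tss <- ifelse(as.character(strand(g)) == "+", start(g), end(g))
    names(tss) <- S4Vectors::mcols(g)$gene_id
    tss
}

setMethod("show", "GenomeModel", function(object) {
    cat("GenomeModel:", length(object@chromSizes), "chromosome(s),",
        length(object@genes), "gene(s)\n")
    cat("  total length:", sum(as.numeric(object@chromSizes)), "bp\n")
})

#' Construct a SignalTrack
#'
#' @param values named list of per-chromosome numeric vectors.
#' @param binSize bin width (bases).
#' @param chromSizes named chromosome lengths (bases).
#' @param sampleId,mark,condition labels.
#' @param nReads total reads behind the track (`NA` if unknown).
#' @param meta list of processing records.
#' @return A [SignalTrack-class] object.
#' @export
SignalTrack <- function(values, binSize, chromSizes, sampleId = "sample",
                        mark = "mark", condition = "condition",
                        nReads = NA_real_, meta = list()) {
    cs <- as.integer(chromSizes)
    names(cs) <- names(chromSizes)
    new("SignalTrack", binSize = as.integer(binSize), chromSizes = cs,
        values = lapply(values, as.numeric), sampleId = sampleId,
        mark = mark, condition = condition, nReads = as.numeric(nReads),
        meta = meta)
}

#' @describeIn SignalTrack bin width in bases.
#' @param x a `SignalTrack`.
#' @export
setMethod("binSize", "SignalTrack", function(x) x@binSize)

#' @describeIn SignalTrack per-chromosome value vectors.
#' @export
setMethod("trackValues", "SignalTrack", function(x) x@values)

#' @describeIn SignalTrack chromosome lengths.
#' @export
setMethod("chromSizes", "SignalTrack", function(x) x@chromSizes)

#' @describeIn SignalTrack total number of genome bins.
#' @export
setMethod("nBins", "SignalTrack", function(x) sum(lengths(x@values)))

#' @describeIn SignalTrack genome-wide mean intensity over all bins.
#' @export
setMethod("trackMean", "SignalTrack",
          function(x) sum(unlist(x@values, use.names = FALSE)) / nBins(x))

#' @describeIn SignalTrack sample label.
#' @export
setMethod("sampleId", "SignalTrack", function(x) x@sampleId)

#' @describeIn SignalTrack histone-mark label.
#' @export
setMethod("trackMark", "SignalTrack", function(x) x@mark)

#' @describeIn SignalTrack condition label.
#' @export
setMethod("trackCondition", "SignalTrack", function(x) x@condition)

#' @describeIn SignalTrack processing records (scaling factor,
#'   calibration level, subtraction parameters).
#' @export
setMethod("trackMeta", "SignalTrack", function(x) x@meta)

setMethod("show", "SignalTrack", function(object) {
    cat(sprintf("SignalTrack %s [%s, %s]: %d bins of %d bp, mean %.4g\n",
                object@sampleId, object@mark, object@condition,
                nBins(object), object@binSize, trackMean(object)))
    if (length(object@meta))
        cat("  processing:", paste(names(object@meta), collapse = " -> "), "\n")
})

#' Construct a CalibrationTable
#'
#' @param table data.frame with columns `sample_id`, `mark`,
#'   `global_level`; exactly one reference row (level 1) per mark.
#' @return A [CalibrationTable-class] object.
#' @export
CalibrationTable <- function(table) {
    table$sample_id <- as.character(table$sample_id)
    table$mark <- as.character(table$mark)
    table$global_level <- as.numeric(table$global_level)
    new("CalibrationTable", table = table[, c("sample_id", "mark", "global_level")])
}

#' @describeIn CalibrationTable global level for one (sample, mark);
#'   errors if absent.
#' @param x a `CalibrationTable`.
#' @param sample,mark labels to look up.
#' @export
setMethod("globalLevel", "CalibrationTable", function(x, sample, mark) {
    tb <- x@table
    hit <- tb$sample_id == sample & tb$mark == mark
    if (sum(hit) != 1L)
        stop(sprintf("no calibration row for sample '%s', mark '%s'", sample, mark))
    tb$global_level[hit]
})

#' @describeIn CalibrationTable the reference sample (level 1) of a mark.
#' @export
setMethod("referenceSample", "CalibrationTable", function(x, mark) {
    tb <- x@table
    tb$sample_id[tb$mark == mark & tb$global_level == 1]
})

#' @describeIn CalibrationTable underlying data.frame.
#' @param object a `CalibrationTable`.
#' @export
calibrationTable <- function(object) object@table

setMethod("show", "CalibrationTable", function(object) {
    cat("CalibrationTable with", nrow(object@table), "row(s):\n")
    print(object@table, row.names = FALSE)
})

#' Construct an ExpressionTable
#'
#' @param counts gene x sample matrix of non-negative integer read
#'   counts with rownames (gene ids) and colnames (sample ids).
#' @param exonicLength per-gene exonic length in bp (recycled names from
#'   `counts` rownames).
#' @param librarySize per-sample mapped reads; defaults to the column
#'   sums of `counts`.
#' @return An [ExpressionTable-class] object.
#' @examples
#' cnt <- matrix(c(10L, 0L, 5L, 20L), 2, 2,
#'               dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' et <- ExpressionTable(cnt, exonicLength = c(1000, 2000),
#'                       librarySize = c(1e6, 1e6))
#' rpkm(computeRPKM(et))
#' @export
ExpressionTable <- function(counts, exonicLength,
                            librarySize = colSums(counts)) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(exonic_length_bp = as.numeric(exonicLength),
                                       row.names = rownames(counts)),
        colData = S4Vectors::DataFrame(library_size = as.numeric(librarySize),
                                       row.names = colnames(counts)))
    new("ExpressionTable", se)
}

#' @describeIn ExpressionTable RPKM assay (errors until [computeRPKM()]
#'   has been applied).
#' @param x an `ExpressionTable`.
#' @export
setMethod("rpkm", "ExpressionTable", function(x) {
    if (!"rpkm" %in% SummarizedExperiment::assayNames(x))
        stop("no rpkm assay: call computeRPKM() first")
    SummarizedExperiment::assay(x, "rpkm")
})

#' @describeIn ExpressionTable per-gene exonic lengths (bp).
#' @export
setMethod("exonicLengths", "ExpressionTable",
          function(x) {
              v <- SummarizedExperiment::rowData(x)$exonic_length_bp
              names(v) <- rownames(x)
              v
          })

#' @describeIn ExpressionTable per-sample mapped-read totals.
#' @export
setMethod("librarySizes", "ExpressionTable",
          function(x) {
              v <- SummarizedExperiment::colData(x)$library_size
              names(v) <- colnames(x)
              v
          })

#' @describeIn ExpressionTable gene identifiers.
#' @export
setMethod("geneIds", "ExpressionTable", function(x) rownames(x))

#' Construct a GenePartition
#'
#' @param scheme label of the classification rule.
#' @param sets named list of disjoint gene-id character vectors.
#' @param params named list of rule parameters (threshold, pseudocount).
#' @return A [GenePartition-class] object.
#' @export
GenePartition <- function(scheme, sets, params = list()) {
    sets <- lapply(sets, as.character)
    new("GenePartition", scheme = scheme, sets = sets, params = params)
}

#' @describeIn GenePartition named list of gene-id sets.
#' @param x a `GenePartition`.
#' @export
setMethod("partitionSets", "GenePartition", function(x) x@sets)

#' @describeIn GenePartition parameters the rule used.
#' @export
setMethod("partitionParams", "GenePartition", function(x) x@params)

#' @describeIn GenePartition scheme label.
#' @export
setMethod("scheme", "GenePartition", function(x) x@scheme)

setMethod("show", "GenePartition", function(object) {
    cat(sprintf("GenePartition '%s':\n", object@scheme))
    for (nm in names(object@sets))
        cat(sprintf("  %-12s %d gene(s)\n", nm, length(object@sets[[nm]])))
    if (length(object@params)) {
        p <- paste(names(object@params), unlist(object@params), sep = "=")
        cat("  params:", paste(p, collapse = ", "), "\n")
    }
})

#' @describeIn ProfileMatrix sub-window centre offsets (bases from TSS).
#' @param x a `ProfileMatrix`.
#' @export
setMethod("profileOffsets", "ProfileMatrix", function(x) x@offsets)

#' @describeIn ProfileMatrix genes x offsets intensity matrix.
#' @export
setMethod("intensityMatrix", "ProfileMatrix", function(x) x@mat)

#' @describeIn ProfileMatrix per-group mean curves (groups x offsets
#'   matrix).
#' @export
setMethod("groupCurves", "ProfileMatrix", function(x) {
    out <- t(vapply(x@groups, function(ids) {
        colMeans(x@mat[ids, , drop = FALSE])
    }, numeric(length(x@offsets))))
    colnames(out) <- x@offsets
    out
})

setMethod("show", "ProfileMatrix", function(object) {
    cat(sprintf("ProfileMatrix: %d gene(s) x %d offsets (%+d..%+d bp), %d group(s)\n",
                nrow(object@mat), length(object@offsets),
                as.integer(min(object@offsets)), as.integer(max(object@offsets)),
                length(object@groups)))
    if (object@dropped > 0L)
        cat("  dropped", object@dropped, "gene(s) with out-of-bounds windows\n")
})

#' @describeIn SelectivityRanking full ranking table.
#' @param x a `SelectivityRanking`.
#' @export
setMethod("rankingTable", "SelectivityRanking", function(x) x@table)

#' @describeIn SelectivityRanking gene ids selected on one side
#'   (`"A"` or `"B"`), in rank order.
#' @param side `"A"` or `"B"`.
#' @export
setMethod("selectedGenes", "SelectivityRanking", function(x, side) {
    side <- match.arg(side, c("A", "B"))
    tb <- x@table[!is.na(x@table$selected) & x@table$selected == side, ]
    tb$gene_id[order(tb$rank)]
})

setMethod("show", "SelectivityRanking", function(object) {
    cat(sprintf("SelectivityRanking %s vs %s: %d gene(s), top %d per direction\n",
                object@labels[["A"]], object@labels[["B"]],
                nrow(object@table), object@topN))
    cat(sprintf("  selected: %d A-selective, %d B-selective\n",
                sum(object@table$selected == "A", na.rm = TRUE),
                sum(object@table$selected == "B", na.rm = TRUE)))
})
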