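#' @importFrom S4Vectors metadata isSorted
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Parameters of the synthetic ground-truth generator
#'
#' A `SyntheticSpec` bundles every knob of the toy-genome simulator:
#' genome geometry, the Poisson read model, the planted chromatin
#' enrichment domains, the global depletion factor applied to the mutant
#' condition, and the planted expression program (induced and
#' mutant-sensitive gene fractions).  One integer seed drives all random
#' streams; each (mark, condition) sample derives an independent
#' substream so adding a sample never perturbs the others.
#'
#' @slot nChroms number of chromosomes.
#' @slot chromLength length of each chromosome in bases; must be a
#'   multiple of `binSize`.
#' @slot nGenes number of non-overlapping genes to place.
#' @slot binSize bin width in bases for read simulation and coverage.
#' @slot enrichmentDomains list of two-element numeric vectors
#'   `c(fraction, fold)`: each plants `fold`-enrichment over background on
#'   the gene bodies of a `fraction` of genes.
#' @slot globalDepletion factor in (0, 1] multiplying the mutant
#'   condition's expected ChIP rate uniformly (1 = no depletion).
#' @slot backgroundRate expected reads per bin away from enriched domains.
#' @slot inducedFraction fraction of genes planted as >= `inducedFold`
#'   induced from D0 to D2 in the control condition.
#' @slot sensitiveFraction fraction of induced genes that fail to be
#'   induced in the mutant condition.
#' @slot inducedFold true fold change planted for induced genes.
#' @slot noiseSd standard deviation of log-normal multiplicative noise on
#'   expression means (natural-log scale); 0 gives the noiseless mode.
#' @slot readLength simulated single-end read length in bases.
#' @slot seed integer master seed.
#'
#' @seealso [syntheticSpec()], [makeGenome()], [simulateChipReads()],
#'   [simulateExpression()]
#' @export
setClass("SyntheticSpec", representation(
    nChroms = "integer",
    chromLength = "integer",
    nGenes = "integer",
    binSize = "integer",
    enrichmentDomains = "list",
    globalDepletion = "numeric",
    backgroundRate = "numeric",
    inducedFraction = "numeric",
    sensitiveFraction = "numeric",
    inducedFold = "numeric",
    noiseSd = "numeric",
    readLength = "integer",
    seed = "integer"
))

setValidity("SyntheticSpec", function(object) {
    msg <- character()
    if (object@nChroms < 1L) msg <- c(msg, "nChroms must be >= 1")
    if (object@chromLength < object@binSize)
        msg <- c(msg, "chromLength must be >= binSize")
    if (object@chromLength %% object@binSize != 0L)
        msg <- c(msg, "chromLength must be divisible by binSize")
    if (object@nGenes < 0L) msg <- c(msg, "nGenes must be >= 0")
    fr <- c(object@inducedFraction, object@sensitiveFraction)
    if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
    if (object@globalDepletion <= 0 || object@globalDepletion > 1)
        msg <- c(msg, "globalDepletion must lie in (0, 1]")
    if (object@backgroundRate <= 0) msg <- c(msg, "backgroundRate must be > 0")
    if (object@inducedFold <= 1) msg <- c(msg, "inducedFold must be > 1")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    for (d in object@enrichmentDomains) {
        if (length(d) != 2L || d[1] < 0 || d[1] > 1 || d[2] <= 0)
            msg <- c(msg, "each enrichment domain must be c(fraction in [0,1], fold > 0)")
    }
    if (length(msg)) msg else TRUE
})

#' Toy genome: chromosome sizes plus gene annotation
#'
#' Chromosome lengths and a `GRanges` of gene bodies carrying
#' `gene_id` and `exonic_length` metadata columns.  Coordinates are
#' 1-based closed (the native `GRanges` convention); readers and writers
#' convert from/to each file format's dialect.  The TSS of a gene is its
#' `start` on the + strand and its `end` on the - strand.
#'
#' @slot chromSizes named integer vector of chromosome lengths (bases).
#' @slot genes `GRanges` with metadata columns `gene_id` (unique) and
#'   `exonic_length` (bases, in `[1, width]`).
#'
#' @seealso [GenomeModel()], [readAnnotation()], [tssPositions()]
#' @export
setClass("GenomeModel", representation(
    chromSizes = "integer",
    genes = "GRanges"
))

setValidity("GenomeModel", function(object) {
    msg <- character()
    cs <- object@chromSizes
    if (is.null(names(cs)) || anyDuplicated(names(cs)))
        msg <- c(msg, "chromSizes must have unique names")
    if (any(cs < 1L)) msg <- c(msg, "chromosome lengths must be positive")
    g <- object@genes
    if (length(g)) {
        mc <- S4Vectors::mcols(g)
        if (!all(c("gene_id", "exonic_length") %in% colnames(mc)))
            return("genes must carry gene_id and exonic_length metadata columns")
        if (anyDuplicated(mc$gene_id)) msg <- c(msg, "gene_ids must be unique")
        if (!all(as.character(seqnames(g)) %in% names(cs)))
            msg <- c(msg, "gene on unknown chromosome")
        else {
            lim <- cs[as.character(seqnames(g))]
            if (any(start(g) < 1L) || any(end(g) > lim))
                msg <- c(msg, "gene interval outside chromosome bounds")
        }
        if (any(mc$exonic_length < 1L) || any(mc$exonic_length > width(g)))
            msg <- c(msg, "exonic_length must lie in [1, gene width]")
        if (any(!as.character(strand(g)) %in% c("+", "-")))
            msg <- c(msg, "gene strand must be + or -")
    }
    if (length(msg)) msg else TRUE
})

#' Binned signal track over a genome
#'
#' Fixed-bin numeric intensity for one sample/mark/condition.  Values are
#' raw binned coverage straight after [computeCoverage()]; dimensionless
#' normalized intensity after [scaleToUnitMean()]; globally calibrated
#' intensity (genome-wide mean equal to the sample's global modification
#' level) after [applyGlobalCalibration()].  The `meta` list logs every
#' factor applied so a manifest can be reconstructed.
#'
#' @slot binSize bin width in bases.
#' @slot chromSizes named integer vector of chromosome lengths.
#' @slot values named list (one numeric vector per chromosome) of length
#'   `ceiling(chromLength / binSize)` each.
#' @slot sampleId,mark,condition character labels.
#' @slot nReads total reads the track was computed from (`NA` if unknown;
#'   needed to depth-match the Poisson input subtraction).
#' @slot meta list of processing records (scale factor, calibration
#'   level, subtraction parameters).
#'
#' @seealso [SignalTrack()], [computeCoverage()], [subtractInput()]
#' @export
setClass("SignalTrack", representation(
    binSize = "integer",
    chromSizes = "integer",
    values = "list",
    sampleId = "character",
    mark = "character",
    condition = "character",
    nReads = "numeric",
    meta = "list"
))

setValidity("SignalTrack", function(object) {
    msg <- character()
    cs <- object@chromSizes
    v <- object@values
    if (!identical(sort(names(v)), sort(names(cs))))
        return("values must have one vector per chromosome in chromSizes")
    for (ch in names(cs)) {
        expect <- as.integer(ceiling(cs[[ch]] / object@binSize))
        if (length(v[[ch]]) != expect)
            msg <- c(msg, sprintf("chromosome %s: %d bins, expected %d",
                                  ch, length(v[[ch]]), expect))
        if (any(!is.finite(v[[ch]]))) msg <- c(msg, sprintf("non-finite values on %s", ch))
        if (any(v[[ch]] < 0)) msg <- c(msg, sprintf("negative values on %s", ch))
    }
    if (object@binSize < 1L) msg <- c(msg, "binSize must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Per-sample global modification levels (Western-blot factors)
#'
#' One row per (sample, mark): the sample's global modification level as
#' a unitless ratio relative to the reference sample of that mark.  The
#' reference has level exactly 1 and there is exactly one per mark.  This
#' is the quantity a Western blot measures and is what rescales unit-mean
#' tracks so genuine global differences between samples survive
#' normalization.
#'
#' @slot table data.frame with columns `sample_id`, `mark`,
#'   `global_level`.
#'
#' @seealso [CalibrationTable()], [readCalibration()],
#'   [applyGlobalCalibration()]
#' @export
setClass("CalibrationTable", representation(table = "data.frame"))

setValidity("CalibrationTable", function(object) {
    tb <- object@table
    need <- c("sample_id", "mark", "global_level")
    if (!all(need %in% colnames(tb)))
        return("table must have columns sample_id, mark, global_level")
    msg <- character()
    if (any(!is.finite(tb$global_level)) || any(tb$global_level <= 0))
        msg <- c(msg, "global_level must be finite and > 0")
    if (anyDuplicated(tb[, c("sample_id", "mark")]))
        msg <- c(msg, "duplicate (sample_id, mark) rows")
    for (m in unique(tb$mark)) {
        nref <- sum(tb$global_level[tb$mark == m] == 1)
        if (nref != 1L)
            msg <- c(msg, sprintf("mark %s: %d reference samples (global_level == 1), need exactly 1",
                                  m, nref))
    }
    if (length(msg)) msg else TRUE
})

#' Gene-by-sample expression container
#'
#' Extends `SummarizedExperiment`: assay `counts` (raw reads per gene and
#' sample), optional assay `rpkm` added by [computeRPKM()], rowData
#' column `exonic_length_bp`, colData column `library_size` (mapped
#' reads).
#'
#' @seealso [ExpressionTable()], [computeRPKM()], [callRegulated()]
#' @export
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
setClass("ExpressionTable", contains = "SummarizedExperiment")

setValidity("ExpressionTable", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0) || any(cnt != round(cnt)))
        msg <- c(msg, "counts must be non-negative integers")
    rd <- SummarizedExperiment::rowData(object)
    if (!"exonic_length_bp" %in% colnames(rd))
        msg <- c(msg, "rowData column exonic_length_bp is required")
    else if (any(rd$exonic_length_bp <= 0))
        msg <- c(msg, "exonic_length_bp must be > 0")
    cd <- SummarizedExperiment::colData(object)
    if (!"library_size" %in% colnames(cd))
        msg <- c(msg, "colData column library_size is required")
    else {
        if (any(cd$library_size <= 0)) msg <- c(msg, "library_size must be > 0")
        if (any(cd$library_size < colSums(cnt)))
            msg <- c(msg, "library_size must be >= column sum of counts")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "unique gene ids (rownames) are required")
    if (length(msg)) msg else TRUE
})

#' Named disjoint gene sets from a classification rule
#'
#' The result of a gene-classification rule: a scheme label (e.g.
#' "regulation" or "sensitivity"), named disjoint sets of gene ids (e.g.
#' up/down/unchanged or sensitive/resistant), and the parameters the rule
#' used (fold threshold, pseudocount) so every call is reproducible from
#' the object alone.
#'
#' @slot scheme character label for the rule that produced the partition.
#' @slot sets named list of disjoint character vectors of gene ids.
#' @slot params named list of the rule's parameters.
#'
#' @seealso [GenePartition()], [callRegulated()], [partitionSensitivity()]
#' @export
setClass("GenePartition", representation(
    scheme = "character",
    sets = "list",
    params = "list"
))

setValidity("GenePartition", function(object) {
    msg <- character()
    s <- object@sets
    if (length(s) && (is.null(names(s)) || any(names(s) == "")))
        msg <- c(msg, "sets must be named")
    all_ids <- unlist(s, use.names = FALSE)
    if (anyDuplicated(all_ids)) msg <- c(msg, "sets must be disjoint")
    if (length(msg)) msg else TRUE
})

#' Strand-flipped TSS metagene matrix
#'
#' Per-gene calibrated intensity in fixed-width sub-windows around the
#' TSS, rows strand-flipped so positive offsets are downstream in the
#' transcription sense.  Offsets are sub-window centres, symmetric about
#' 0.  Group mean curves are available via [groupCurves()].
#'
#' @slot offsets numeric vector of sub-window centres (bases relative to
#'   TSS).
#' @slot mat genes x offsets matrix of intensity (rownames = gene ids).
#' @slot groups named list of gene-id vectors defining the metagene
#'   groups.
#' @slot dropped number of genes discarded because their window exceeded
#'   chromosome bounds.
#'
#' @seealso [tssProfile()], [ratioProfile()]
#' @export
setClass("ProfileMatrix", representation(
    offsets = "numeric",
    mat = "matrix",
    groups = "list",
    dropped = "integer"
))

setValidity("ProfileMatrix", function(object) {
    msg <- character()
    if (ncol(object@mat) != length(object@offsets))
        msg <- c(msg, "matrix columns must match offsets")
    if (max(abs(object@offsets + rev(object@offsets))) > 1e-9)
        msg <- c(msg, "offsets must be symmetric about 0")
    if (!all(unlist(object@groups) %in% rownames(object@mat)))
        msg <- c(msg, "group members must be matrix rows")
    if (length(msg)) msg else TRUE
})

#' Ranked depot-selectivity table
#'
#' Per-gene log2 fold change between two conditions, a strict
#' deterministic ranking, and top-N selection flags in each direction
#' ("A" for the most A-selective genes, "B" for the most B-selective).
#'
#' @slot table data.frame with columns `gene_id`, `log2fc`, `rank`,
#'   `selected` (`"A"`, `"B"` or `NA`).
#' @slot labels named character vector `c(A = , B = )` of the contrasted
#'   sample labels.
#' @slot topN selection size per direction actually used.
#' @slot pseudocount pseudocount added to both RPKM values.
#'
#' @seealso [rankSelectivity()], [heatmapMatrix()]
#' @export
setClass("SelectivityRanking", representation(
    table = "data.frame",
    labels = "character",
    topN = "integer",
    pseudocount = "numeric"
))

setValidity("SelectivityRanking", function(object) {
    tb <- object@table
    need <- c("gene_id", "log2fc", "rank", "selected")
    if (!all(need %in% colnames(tb)))
        return("table must have columns gene_id, log2fc, rank, selected")
    msg <- character()
    if (anyDuplicated(tb$rank)) msg <- c(msg, "ranks must be unique")
    for (side in c("A", "B")) {
        n <- sum(tb$selected == side, na.rm = TRUE)
        if (n > object@topN)
            msg <- c(msg, sprintf("more than topN genes selected on side %s", side))
    }
    if (length(msg)) msg else TRUE
})
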