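#' @importFrom rtracklayer import export
#' @importFrom utils read.delim write.table count.fields
NULL

## Pre-scan a BED-family file for lines with the wrong field count so the
## error can name the offending line; rtracklayer then does the real parse.
checkFieldCounts <- function(path, min_fields) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    n <- count.fields(con, sep = "\t", quote = "", comment.char = "#",
                      blank.lines.skip = TRUE)
    bad <- which(!is.na(n) & n < min_fields)
    if (length(bad))
        stop(sprintf("%s: line %d has %d field(s), expected >= %d",
                     basename(path), bad[1], n[bad[1]], min_fields))
    invisible(TRUE)
}

#' Read gene annotation into a GenomeModel
#'
#' Accepts BED12 (also plain 6-column BED) or GTF.  File coordinates are
#' converted to the internal 1-based closed convention on input (BED is
#' 0-based half-open, GTF 1-based closed).  For BED12 the exonic length
#' is the sum of block sizes; for GTF it is the sum of reduced `exon`
#' widths per `gene_id`, and the gene body is the span of its exons.
#'
#' @param path BED or GTF file (gzip transparent).
#' @param format `"bed12"` or `"gtf"`.
#' @param chromSizes named chromosome lengths; if `NULL` they are
#'   inferred as the maximum end per chromosome.
#' @return A [GenomeModel-class].  A gene extending beyond a supplied
#'   chromosome length is an error.
#' @export
readAnnotation <- function(path, format = c("bed12", "gtf"),
                           chromSizes = NULL) {
    format <- match.arg(format)
    if (format == "bed12") {
        checkFieldCounts(path, 6L)
        gr <- import(path, format = "BED")
        if (is.null(gr$name) || anyDuplicated(gr$name))
            stop("BED annotation requires unique gene names in column 4")
        exonic <- if (!is.null(gr$blocks))
            vapply(gr$blocks, function(b) sum(width(b)), integer(1))
        else width(gr)
        g <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                     strand = strand(gr))
        S4Vectors::mcols(g)$gene_id <- gr$name
        S4Vectors::mcols(g)$exonic_length <- as.integer(exonic)
    } else {
        gr <- import(path, format = "gtf")
        ex <- gr[gr$type == "exon"]
        if (length(ex) == 0L) stop("GTF has no exon records")
        if (is.null(ex$gene_id) || anyNA(ex$gene_id))
            stop("GTF exon records must carry a gene_id attribute")
        gid <- ex$gene_id
        ids <- sort(unique(gid))
        span_start <- tapply(start(ex), gid, min)[ids]
        span_end <- tapply(end(ex), gid, max)[ids]
        chrom <- tapply(as.character(seqnames(ex)), gid, `[`, 1)[ids]
        strands <- tapply(as.character(strand(ex)), gid, `[`, 1)[ids]
        exonic <- vapply(split(ex, gid)[ids], function(e)
            sum(width(GenomicRanges::reduce(e, ignore.strand = TRUE))),
            integer(1))
        g <- GRanges(chrom, IRanges(as.integer(span_start),
                                    as.integer(span_end)),
                     strand = strands)
        S4Vectors::mcols(g)$gene_id <- ids
        S4Vectors::mcols(g)$exonic_length <- as.integer(exonic)
    }
    if (any(!as.character(strand(g)) %in% c("+", "-")))
        stop("every gene must have strand + or -")
    if (is.null(chromSizes)) {
        ends <- tapply(end(g), as.character(seqnames(g)), max)
        chromSizes <- setNames(as.integer(ends), names(ends))
    }
    GenomeModel(chromSizes, sort(g, ignore.strand = TRUE))
}

#' Write a GenomeModel's genes as BED12
#'
#' Each gene is written with its exonic length realized as two blocks
#' anchored at the gene ends (one block when the gene is fully exonic),
#' so `readAnnotation()` round-trips gene span, strand and exonic length
#' exactly.  Output is 0-based half-open per the BED standard.
#'
#' @param genome a [GenomeModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(genome, path) {
    g <- genes(genome)
    if (length(g) == 0L) {
        writeLines(character(0), path)
        return(invisible(path))
    }
    exonic <- S4Vectors::mcols(g)$exonic_length
    w <- width(g)
    blocks <- IRanges::IRangesList(lapply(seq_along(g), function(i) {
        if (exonic[i] >= w[i]) return(IRanges(1L, w[i]))
        e1 <- max(1L, exonic[i] %/% 2L)
        e2 <- exonic[i] - e1
        if (e2 == 0L) return(IRanges(1L, exonic[i]))
        IRanges(start = c(1L, w[i] - e2 + 1L), width = c(e1, e2))
    }))
    out <- GRanges(seqnames(g), IRanges(start(g), end(g)), strand = strand(g))
    out$name <- S4Vectors::mcols(g)$gene_id
    out$score <- 0L
    out$thick <- IRanges(start(g), end(g))
    out$blocks <- blocks
    export(out, path, format = "BED")
    invisible(path)
}

#' Write / read a two-column chromosome-sizes file
#'
#' @param chromSizes named integer vector.
#' @param path TSV file `chrom<TAB>length`.
#' @return `writeChromSizes` returns `path` invisibly; `readChromSizes`
#'   the named vector.
#' @export
writeChromSizes <- function(chromSizes, path) {
    write.table(data.frame(names(chromSizes), as.integer(chromSizes)),
                path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' @rdname writeChromSizes
#' @export
readChromSizes <- function(path) {
    df <- read.delim(path, header = FALSE)
    setNames(as.integer(df[[2]]), as.character(df[[1]]))
}

#' Read aligned-read intervals from BED
#'
#' @param path BED file with at least 3 columns (gzip transparent).
#' @param chromSizes optional named lengths used to validate intervals.
#' @param unknownChrom `"error"` (default) or `"skip"`: what to do with
#'   reads on chromosomes absent from `chromSizes`; skipped reads are
#'   counted in a warning.
#' @return A `GRanges` of read intervals (1-based closed).  An interval
#'   ending beyond its chromosome is always an error.
#' @export
readReads <- function(path, chromSizes = NULL,
                      unknownChrom = c("error", "skip")) {
    unknownChrom <- match.arg(unknownChrom)
    checkFieldCounts(path, 3L)
    gr <- import(path, format = "BED")
    if (!is.null(chromSizes)) {
        known <- as.character(seqnames(gr)) %in% names(chromSizes)
        if (!all(known)) {
            if (unknownChrom == "error")
                stop(sum(!known), " read(s) on chromosomes absent from chromSizes")
            warning("skipping ", sum(!known), " read(s) on unknown chromosomes")
            gr <- gr[known]
        }
        if (length(gr)) {
            lim <- chromSizes[as.character(seqnames(gr))]
            if (any(end(gr) > lim) || any(start(gr) < 1L))
                stop("read interval outside chromosome bounds")
        }
    }
    message(length(gr), " read(s) loaded from ", basename(path))
    gr
}

#' Write read intervals as 6-column BED
#'
#' @param reads a `GRanges`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeReads <- function(reads, path) {
    out <- reads
    out$name <- sprintf("r%d", seq_along(out))
    out$score <- 0L
    export(out, path, format = "BED")
    invisible(path)
}

#' Write a SignalTrack as bedGraph
#'
#' Values are written with 6 significant digits; adjacent bins with equal
#' (rounded) values are merged into one interval, zero-coverage regions
#' are written explicitly (no gaps), and the final interval of each
#' chromosome is clipped to the chromosome end.
#'
#' @param track a [SignalTrack-class].
#' @param path output bedGraph file.
#' @return `path`, invisibly.
#' @export
writeTrack <- function(track, path) {
    cs <- chromSizes(track)
    bs <- binSize(track)
    per <- lapply(names(cs), function(ch) {
        v <- signif(trackValues(track)[[ch]], 6)
        r <- rle(v)
        ends_bin <- cumsum(r$lengths)
        starts <- (c(0L, ends_bin[-length(ends_bin)])) * bs + 1L
        ends <- pmin(ends_bin * bs, cs[[ch]])
        GRanges(ch, IRanges(starts, ends), score = r$values)
    })
    gr <- suppressWarnings(do.call(c, per))
    export(gr, path, format = "bedGraph")
    invisible(path)
}

#' Read a bedGraph file into a SignalTrack
#'
#' Intervals must align to the bin grid (the final interval of a
#' chromosome may be clipped to the chromosome end).  Uncovered bins
#' become 0.
#'
#' @param path bedGraph file.
#' @param binSize bin width (bases).
#' @param chromSizes named chromosome lengths.
#' @param sampleId,mark,condition labels attached to the track.
#' @return A [SignalTrack-class].
#' @export
readTrack <- function(path, binSize, chromSizes, sampleId = "sample",
                      mark = "mark", condition = "condition") {
    gr <- import(path, format = "bedGraph")
    vals <- lapply(names(chromSizes), function(ch)
        numeric(ceiling(chromSizes[[ch]] / binSize)))
    names(vals) <- names(chromSizes)
    if (length(gr)) {
        if (any(!as.character(seqnames(gr)) %in% names(chromSizes)))
            stop("bedGraph interval on chromosome absent from chromSizes")
        b1 <- (start(gr) - 1L) %/% binSize + 1L
        b2 <- (end(gr) - 1L) %/% binSize + 1L
        if (any((start(gr) - 1L) %% binSize != 0L))
            stop("bedGraph intervals do not align to the ", binSize, " bp bin grid")
        for (i in seq_along(gr)) {
            ch <- as.character(seqnames(gr))[i]
            vals[[ch]][b1[i]:b2[i]] <- gr$score[i]
        }
    }
    SignalTrack(vals, binSize, chromSizes, sampleId = sampleId,
                mark = mark, condition = condition)
}

#' Read / write a Western-blot calibration table
#'
#' The TSV must have columns `sample_id`, `mark`, `global_level`
#' (unitless, relative to the mark's reference sample).  Validation
#' enforces positive levels, no duplicate (sample, mark) rows and exactly
#' one reference (level 1) per mark.
#'
#' @param path TSV file.
#' @return `readCalibration` returns a [CalibrationTable-class].
#' @export
readCalibration <- function(path) {
    df <- read.delim(path, check.names = FALSE)
    need <- c("sample_id", "mark", "global_level")
    if (!all(need %in% colnames(df)))
        stop("calibration table must have columns: ",
             paste(need, collapse = ", "))
    CalibrationTable(df)
}

#' @rdname readCalibration
#' @param calib a [CalibrationTable-class].
#' @export
writeCalibration <- function(calib, path) {
    write.table(calibrationTable(calib), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Write / read an ExpressionTable as TSV
#'
#' Layout: header comment lines `#library_size sample=value`, then
#' columns `gene_id`, `length_bp` and one raw-count column per sample.
#' The round trip is lossless.
#'
#' @param expr an [ExpressionTable-class].
#' @param path TSV file.
#' @return `writeExpression` returns `path` invisibly; `readExpression`
#'   an [ExpressionTable-class].
#' @export
writeExpression <- function(expr, path) {
    cnt <- SummarizedExperiment::assay(expr, "counts")
    lib <- librarySizes(expr)
    hdr <- sprintf("#library_size\t%s=%s", names(lib),
                   format(lib, scientific = FALSE, trim = TRUE))
    df <- data.frame(gene_id = rownames(expr),
                     length_bp = as.integer(exonicLengths(expr)),
                     cnt, check.names = FALSE)
    con <- file(path, "wt")
    on.exit(close(con))
    writeLines(hdr, con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeExpression
#' @export
readExpression <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^#library_size\t", lines, value = TRUE)
    df <- read.delim(text = lines[!startsWith(lines, "#")],
                     check.names = FALSE)
    if (!all(c("gene_id", "length_bp") %in% colnames(df)))
        stop("expression table must have gene_id and length_bp columns")
    if (nrow(df) == 0L) stop("expression table has no genes")
    cnt <- as.matrix(df[, setdiff(colnames(df), c("gene_id", "length_bp")),
                        drop = FALSE])
    rownames(cnt) <- df$gene_id
    lib <- colSums(cnt)
    if (length(hdr)) {
        kv <- strsplit(sub("^#library_size\t", "", hdr), "=")
        for (p in kv) lib[p[1]] <- as.numeric(p[2])
    }
    ExpressionTable(cnt, exonicLength = df$length_bp, librarySize = lib)
}

#' Write / read a GenePartition as two-column TSV
#'
#' Layout: comment lines `#scheme name` and `#param key=value`, then
#' columns `gene_id`, `set`.
#'
#' @param part a [GenePartition-class].
#' @param path TSV file.
#' @return `writePartition` returns `path` invisibly; `readPartition` a
#'   [GenePartition-class].
#' @export
writePartition <- function(part, path) {
    sets <- partitionSets(part)
    df <- data.frame(gene_id = unlist(sets, use.names = FALSE),
                     set = rep(names(sets), lengths(sets)))
    con <- file(path, "wt")
    on.exit(close(con))
    writeLines(paste0("#scheme\t", scheme(part)), con)
    p <- partitionParams(part)
    if (length(p))
        writeLines(sprintf("#param\t%s=%s", names(p), unlist(p)), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writePartition
#' @export
readPartition <- function(path) {
    lines <- readLines(path)
    sc <- sub("^#scheme\t", "", grep("^#scheme\t", lines, value = TRUE))
    if (!length(sc)) sc <- "unknown"
    pl <- sub("^#param\t", "", grep("^#param\t", lines, value = TRUE))
    params <- list()
    for (p in pl) {
        kv <- strsplit(p, "=")[[1]]
        num <- suppressWarnings(as.numeric(kv[2]))
        params[[kv[1]]] <- if (is.na(num)) kv[2] else num
    }
    df <- read.delim(text = lines[!startsWith(lines, "#")],
                     check.names = FALSE)
    sets <- split(df$gene_id, df$set)
    GenePartition(sc[1], sets, params)
}
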