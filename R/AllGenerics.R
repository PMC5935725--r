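#' @import methods
NULL

#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))

#' @export
setGeneric("genes", function(x, ...) standardGeneric("genes"))

#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @export
setGeneric("trackMean", function(x) standardGeneric("trackMean"))

#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @export
setGeneric("trackMark", function(x) standardGeneric("trackMark"))

#' @export
setGeneric("trackCondition", function(x) standardGeneric("trackCondition"))

#' @export
setGeneric("trackMeta", function(x) standardGeneric("trackMeta"))

#' @export
setGeneric("globalLevel", function(x, sample, mark) standardGeneric("globalLevel"))

#' @export
setGeneric("referenceSample", function(x, mark) standardGeneric("referenceSample"))

#' @export
setGeneric("rpkm", function(x) standardGeneric("rpkm"))

#' @export
setGeneric("exonicLengths", function(x) standardGeneric("exonicLengths"))

#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))

#' @export
setGeneric("partitionSets", function(x) standardGeneric("partitionSets"))

#' @export
setGeneric("partitionParams", function(x) standardGeneric("partitionParams"))

#' @export
setGeneric("scheme", function(x) standardGeneric("scheme"))

#' @export
setGeneric("profileOffsets", function(x) standardGeneric("profileOffsets"))

#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' @export
setGeneric("groupCurves", function(x) standardGeneric("groupCurves"))

#' @export
setGeneric("rankingTable", function(x) standardGeneric("rankingTable"))

#' @export
setGeneric("selectedGenes", function(x, side) standardGeneric("selectedGenes"))

#' @export
setGeneric("scaleToUnitMean", function(x) standardGeneric("scaleToUnitMean"))

#' @export
setGeneric("computeRPKM", function(x) standardGeneric("computeRPKM"))
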