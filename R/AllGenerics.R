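#' @import methods
NULL

#' @rdname PeakSet-class
#' @export
setGeneric("peakRanges", function(x) standardGeneric("peakRanges"))

#' @rdname PeakSet-class
#' @export
setGeneric("peakIds", function(x) standardGeneric("peakIds"))

#' @rdname PeakSet-class
#' @export
setGeneric("subpeakParent", function(x) standardGeneric("subpeakParent"))

#' @rdname PeakSet-class
#' @export
setGeneric("geneAssignments", function(x) standardGeneric("geneAssignments"))

#' @rdname PeakSet-class
#' @export
setGeneric("nearestGene", function(x) standardGeneric("nearestGene"))

#' @rdname PeakSet-class
#' @export
setGeneric("isBidirectional", function(x) standardGeneric("isBidirectional"))

#' @rdname PeakSet-class
#' @export
setGeneric("broadPeaks", function(x) standardGeneric("broadPeaks"))

#' @rdname PeakSet-class
#' @export
setGeneric("subPeaks", function(x) standardGeneric("subPeaks"))

#' @rdname EnrichmentMatrix-class
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' @rdname EnrichmentMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname EnrichmentMatrix-class
#' @export
setGeneric("resolutionType", function(x) standardGeneric("resolutionType"))

#' @rdname EnrichmentMatrix-class
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname EnrichmentMatrix-class
#' @export
setGeneric("enrichValues", function(x) standardGeneric("enrichValues"))

#' @rdname CovariationResult-class
#' @export
setGeneric("selectedIds", function(x) standardGeneric("selectedIds"))

#' @rdname CovariationResult-class
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname CovariationResult-class
#' @export
setGeneric("partnerMap", function(x) standardGeneric("partnerMap"))

#' @rdname CovariationResult-class
#' @export
setGeneric("pcVariance", function(x, ...) standardGeneric("pcVariance"))
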