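#' PeakSet: ChIP-seq peaks with sub-peak structure and promoter annotation
#'
#' A \code{PeakSet} holds a set of called peaks as a \link[GenomicRanges]{GRanges}
#' (metadata columns \code{peak_id}, \code{score}, \code{q_value}), an optional
#' map from nucleosome-sized sub-peaks to their parent broad peak, and the
#' promoter annotation produced by \code{\link{assignPeaks}}: all genes whose
#' promoter window overlaps each peak, the nearest gene, and whether the peak
#' sits in a bidirectional (divergent) promoter.
#'
#' Validity requires unique peak identifiers, q-values in [0, 1], every
#' sub-peak lying within its parent broad peak, and the bidirectional flag
#' implying at least two assigned genes.
#'
#' @slot peaks GRanges with mcols \code{peak_id}, \code{score}, \code{q_value}.
#' @slot subpeakParent named character; names are sub-peak ids, values the
#'   parent broad peak id. Empty when the set has a single resolution.
#' @slot geneAssignments named list of character vectors (peak id -> gene ids).
#' @slot nearestGene named character (peak id -> nearest gene id, NA if none).
#' @slot bidirectional named logical (peak id -> divergent-promoter flag).
#'
#' @param x a \code{PeakSet}
#' @aliases peakRanges peakIds subpeakParent geneAssignments nearestGene
#'   isBidirectional broadPeaks subPeaks
#' @include AllGenerics.R
#' @export
setClass("PeakSet",
  representation(peaks = "GRanges",
                 subpeakParent = "character",
                 geneAssignments = "list",
                 nearestGene = "character",
                 bidirectional = "logical"))

setValidity("PeakSet", function(object) {
  gr <- object@peaks
  msg <- character(0)
  if (is.null(gr$peak_id)) return("peaks must carry a 'peak_id' metadata column")
  ids <- gr$peak_id
  if (anyNA(ids) || anyDuplicated(ids))
    msg <- c(msg, "peak_id values must be unique and non-missing")
  if (!is.null(gr$q_value)) {
    q <- gr$q_value[!is.na(gr$q_value)]
    if (length(q) && (any(q < 0) || any(q > 1)))
      msg <- c(msg, "q_value values must lie in [0, 1]")
  }
  sp <- object@subpeakParent
  if (length(sp)) {
    if (is.null(names(sp)) || !all(names(sp) %in% ids) || !all(sp %in% ids))
      msg <- c(msg, "subpeakParent names and values must be peak ids in the set")
    else {
      child <- gr[match(names(sp), ids)]
      parent <- gr[match(sp, ids)]
      within <- as.character(GenomeInfoDb::seqnames(child)) ==
                  as.character(GenomeInfoDb::seqnames(parent)) &
                GenomicRanges::start(child) >= GenomicRanges::start(parent) &
                GenomicRanges::end(child) <= GenomicRanges::end(parent)
      if (!all(within))
        msg <- c(msg, "every sub-peak must lie within its parent broad peak")
    }
  }
  bd <- object@bidirectional
  if (length(bd)) {
    ga <- object@geneAssignments
    nb <- names(bd)[!is.na(bd) & bd]
    ng <- vapply(ga[nb], length, integer(1))
    if (length(nb) && (!all(nb %in% names(ga)) || any(ng < 2)))
      msg <- c(msg, "bidirectional peaks must have >= 2 assigned genes")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PeakSet
#'
#' @param peaks GRanges with (at least) a \code{peak_id} metadata column;
#'   \code{score} and \code{q_value} columns are added as NA when absent.
#' @param subpeakParent named character mapping sub-peak ids to parent ids.
#' @param geneAssignments,nearestGene,bidirectional annotation slots, normally
#'   filled by \code{\link{assignPeaks}}.
#' @return a \code{PeakSet}
#' @export
PeakSet <- function(peaks, subpeakParent = character(0),
                    geneAssignments = list(), nearestGene = character(0),
                    bidirectional = logical(0)) {
  if (is.null(peaks$peak_id))
    peaks$peak_id <- sprintf("peak_%06d", seq_along(peaks))
  if (is.null(peaks$score)) peaks$score <- NA_real_
  if (is.null(peaks$q_value)) peaks$q_value <- NA_real_
  methods::new("PeakSet", peaks = peaks, subpeakParent = subpeakParent,
               geneAssignments = geneAssignments, nearestGene = nearestGene,
               bidirectional = bidirectional)
}

#' @rdname PeakSet-class
#' @export
setMethod("peakRanges", "PeakSet", function(x) x@peaks)

#' @rdname PeakSet-class
#' @export
setMethod("peakIds", "PeakSet", function(x) x@peaks$peak_id)

#' @rdname PeakSet-class
#' @export
setMethod("subpeakParent", "PeakSet", function(x) x@subpeakParent)

#' @rdname PeakSet-class
#' @export
setMethod("geneAssignments", "PeakSet", function(x) x@geneAssignments)

#' @rdname PeakSet-class
#' @export
setMethod("nearestGene", "PeakSet", function(x) x@nearestGene)

#' @rdname PeakSet-class
#' @export
setMethod("isBidirectional", "PeakSet", function(x) x@bidirectional)

#' @rdname PeakSet-class
#' @export
setMethod("broadPeaks", "PeakSet", function(x) {
  x@peaks[!(x@peaks$peak_id %in% names(x@subpeakParent))]
})

#' @rdname PeakSet-class
#' @export
setMethod("subPeaks", "PeakSet", function(x) {
  x@peaks[x@peaks$peak_id %in% names(x@subpeakParent)]
})

#' @rdname PeakSet-class
#' @export
setMethod("length", "PeakSet", function(x) length(x@peaks))

setMethod("show", "PeakSet", function(object) {
  nsub <- length(object@subpeakParent)
  cat(sprintf("PeakSet with %d peaks (%d broad, %d sub-peaks)\n",
              length(object@peaks), length(object@peaks) - nsub, nsub))
  if (length(object@geneAssignments)) {
    nprom <- sum(vapply(object@geneAssignments, length, integer(1)) > 0)
    cat(sprintf("  promoter-assigned: %d; bidirectional: %d\n",
                nprom, sum(object@bidirectional, na.rm = TRUE)))
  }
})

#' EnrichmentMatrix: region-by-sample ChIP-seq enrichment
#'
#' Extends \link[SummarizedExperiment]{RangedSummarizedExperiment}-free
#' \code{SummarizedExperiment} with the resolution at which regions were
#' quantified (\code{"broad"}, \code{"nucleosome"} or \code{"window"}) and a
#' flag saying whether the single assay holds raw fragment counts or
#' log2-normalized enrichment. Per-sample size factors (when computed) live in
#' \code{colData(x)$sizeFactor}; sample metadata (\code{group}, \code{litter},
#' \code{library_total}) also lives in \code{colData}.
#'
#' @slot resolution character, one of broad / nucleosome / window.
#' @slot normalized logical; TRUE after \code{\link{normalizeLog2}}.
#'
#' @param x an \code{EnrichmentMatrix}
#' @aliases regionIds sampleIds resolutionType isNormalized enrichValues
#' @export
setClass("EnrichmentMatrix",
  contains = "RangedSummarizedExperiment",
  representation(resolution = "character", normalized = "logical"))

setValidity("EnrichmentMatrix", function(object) {
  msg <- character(0)
  if (!object@resolution %in% c("broad", "nucleosome", "window"))
    msg <- c(msg, "resolution must be 'broad', 'nucleosome' or 'window'")
  v <- SummarizedExperiment::assay(object)
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "region ids (rownames) must be present and unique")
  if (!object@normalized) {
    if (any(v < 0) || any(v != floor(v)))
      msg <- c(msg, "raw counts must be non-negative integers")
  }
  sf <- SummarizedExperiment::colData(object)$sizeFactor
  if (!is.null(sf) && any(!is.na(sf) & sf <= 0))
    msg <- c(msg, "size factors must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an EnrichmentMatrix
#'
#' @param values numeric matrix (regions x samples) with rownames (region ids)
#'   and colnames (sample ids).
#' @param resolution one of \code{"broad"}, \code{"nucleosome"}, \code{"window"}.
#' @param sampleMeta optional data.frame of per-sample metadata (rows matched
#'   to columns of \code{values}); typically columns \code{group},
#'   \code{litter}, \code{library_total}.
#' @param normalized logical; FALSE for raw counts.
#' @param sizeFactors optional per-sample positive scalars.
#' @param rowRanges optional GRanges describing the regions.
#' @return an \code{EnrichmentMatrix}
#' @export
EnrichmentMatrix <- function(values, resolution, sampleMeta = NULL,
                             normalized = FALSE, sizeFactors = NULL,
                             rowRanges = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("region_%06d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("sample_%02d", seq_len(ncol(values)))
  cd <- if (is.null(sampleMeta)) S4Vectors::DataFrame(row.names = colnames(values))
        else S4Vectors::DataFrame(sampleMeta, row.names = colnames(values))
  if (!is.null(sizeFactors)) cd$sizeFactor <- sizeFactors
  assayName <- if (normalized) "log2enrich" else "counts"
  assays <- stats::setNames(list(values), assayName)
  if (is.null(rowRanges)) {
    ## coordinate-free matrices get an empty-ranges skeleton (DESeq2-style)
    rowRanges <- IRanges::relist(GenomicRanges::GRanges(),
                                 IRanges::PartitioningByEnd(
                                   integer(nrow(values)),
                                   names = rownames(values)))
  } else {
    names(rowRanges) <- rownames(values)
  }
  se <- SummarizedExperiment::SummarizedExperiment(assays = assays, colData = cd,
                                                   rowRanges = rowRanges)
  methods::new("EnrichmentMatrix", se, resolution = resolution,
               normalized = normalized)
}

#' @rdname EnrichmentMatrix-class
#' @export
setMethod("regionIds", "EnrichmentMatrix", function(x) rownames(x))

#' @rdname EnrichmentMatrix-class
#' @export
setMethod("sampleIds", "EnrichmentMatrix", function(x) colnames(x))

#' @rdname EnrichmentMatrix-class
#' @export
setMethod("resolutionType", "EnrichmentMatrix", function(x) x@resolution)

#' @rdname EnrichmentMatrix-class
#' @export
setMethod("isNormalized", "EnrichmentMatrix", function(x) x@normalized)

#' @rdname EnrichmentMatrix-class
#' @export
setMethod("enrichValues", "EnrichmentMatrix",
          function(x) SummarizedExperiment::assay(x))

#' @rdname EnrichmentMatrix-class
#' @export
setMethod("sizeFactors", "EnrichmentMatrix", function(object) {
  sf <- SummarizedExperiment::colData(object)$sizeFactor
  if (is.null(sf)) return(NULL)
  stats::setNames(sf, colnames(object))
})

#' @rdname EnrichmentMatrix-class
#' @param object an \code{EnrichmentMatrix}; \code{value} replacement factors
#' @param value replacement size factors
#' @export
setMethod("sizeFactors<-", "EnrichmentMatrix", function(object, value) {
  SummarizedExperiment::colData(object)$sizeFactor <- value
  methods::validObject(object)
  object
})

setMethod("show", "EnrichmentMatrix", function(object) {
  cat(sprintf("EnrichmentMatrix: %d regions x %d samples [%s resolution, %s]\n",
              nrow(object), ncol(object), object@resolution,
              if (object@normalized) "log2 normalized" else "raw counts"))
  if (!is.null(SummarizedExperiment::colData(object)$group))
    cat("  groups:", paste(levels(factor(SummarizedExperiment::colData(object)$group)),
                           collapse = ", "), "\n")
})

#' CovariationResult: opposing co-varying peak clusters
#'
#' Result of \code{\link{extractOpposingSubset}} (optionally completed by
#' \code{\link{covariationAnalysis}}): the subset of regions whose enrichment
#' co-varies across individuals, split into two anti-correlated clusters A and
#' B; for each selected region its most negatively correlated partner; and the
#' PCA variance fractions on the full matrix and on the subset, with
#' associations of the PC1 sample scores to metadata factors.
#'
#' @slot selectedIds character; selected region ids.
#' @slot clusterLabel named factor with levels A, B.
#' @slot partner named character (region -> most anti-correlated region).
#' @slot partnerR named numeric (correlation with the partner).
#' @slot pcVarianceFull numeric; per-component variance fractions, full set.
#' @slot pcVarianceSubset numeric; variance fractions on the selected subset.
#' @slot factorAssociation named numeric; p-values of PC1 scores vs metadata.
#'
#' @param x a \code{CovariationResult}
#' @aliases selectedIds clusterLabels partnerMap
#' @export
setClass("CovariationResult",
  representation(selectedIds = "character", clusterLabel = "factor",
                 partner = "character", partnerR = "numeric",
                 pcVarianceFull = "numeric", pcVarianceSubset = "numeric",
                 factorAssociation = "numeric"))

setValidity("CovariationResult", function(object) {
  msg <- character(0)
  if (length(object@selectedIds)) {
    tab <- table(object@clusterLabel)
    if (length(tab) < 2 || any(tab == 0))
      msg <- c(msg, "both clusters must be non-empty when the subset is non-empty")
  }
  for (v in list(object@pcVarianceFull, object@pcVarianceSubset)) {
    if (length(v) && (any(v < -1e-12) || any(v > 1 + 1e-12) || sum(v) > 1 + 1e-8))
      msg <- c(msg, "PC variance fractions must lie in [0,1] and sum to <= 1")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname CovariationResult-class
#' @export
setMethod("selectedIds", "CovariationResult", function(x) x@selectedIds)

#' @rdname CovariationResult-class
#' @export
setMethod("clusterLabels", "CovariationResult", function(x) x@clusterLabel)

#' @rdname CovariationResult-class
#' @export
setMethod("partnerMap", "CovariationResult",
          function(x) data.frame(region = x@selectedIds,
                                 cluster = as.character(x@clusterLabel[x@selectedIds]),
                                 partner = unname(x@partner[x@selectedIds]),
                                 partner_r = unname(x@partnerR[x@selectedIds])))

#' @rdname CovariationResult-class
#' @export
setMethod("pcVariance", "CovariationResult",
          function(x, ...) list(full = x@pcVarianceFull,
                                subset = x@pcVarianceSubset))

setMethod("show", "CovariationResult", function(object) {
  tab <- table(object@clusterLabel)
  cat(sprintf("CovariationResult: %d selected regions (A: %d, B: %d)\n",
              length(object@selectedIds),
              if ("A" %in% names(tab)) tab[["A"]] else 0L,
              if ("B" %in% names(tab)) tab[["B"]] else 0L))
  if (length(object@pcVarianceFull))
    cat(sprintf("  PC1 variance fraction: %.1f%% (full), %.1f%% (subset)\n",
                100 * object@pcVarianceFull[1],
                if (length(object@pcVarianceSubset)) 100 * object@pcVarianceSubset[1] else NA))
})

#' VariabilityProfile: fold-change-over-mean variability summary
#'
#' Per-region log2 fold-changes over the cross-sample mean enrichment,
#' per-sample spread summaries, and the per-sample fraction of regions within
#' a two-fold band of the mean.
#'
#' @slot fcOverMean matrix (regions x samples) of log2 fold-changes over the
#'   row mean (linear scale mean).
#' @slot perSampleSpread data.frame of per-sample spread statistics.
#' @slot fractionWithinTwofold named numeric in [0,1].
#' @export
setClass("VariabilityProfile",
  representation(fcOverMean = "matrix", perSampleSpread = "data.frame",
                 fractionWithinTwofold = "numeric"))

setValidity("VariabilityProfile", function(object) {
  f <- object@fractionWithinTwofold
  if (length(f) && (any(f < 0) || any(f > 1)))
    "fractionWithinTwofold must lie in [0,1]" else TRUE
})

setMethod("show", "VariabilityProfile", function(object) {
  cat(sprintf("VariabilityProfile: %d regions x %d samples\n",
              nrow(object@fcOverMean), ncol(object@fcOverMean)))
  cat(sprintf("  median fraction within two-fold of mean: %.3f\n",
              stats::median(object@fractionWithinTwofold)))
})
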