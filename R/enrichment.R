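## Count matrices, normalization and TSS metaprofiles.

#' Read a per-sample fragment file (BED6 with mapping quality)
#'
#' The BED score column is interpreted as the fragment's mapping quality.
#'
#' @param path BED6 file path
#' @return GRanges with a \code{mapq} metadata column
#' @export
readFragments <- function(path) {
  ps <- readIntervals(path, "bed")
  gr <- peakRanges(ps)
  mapq <- gr$score
  if (anyNA(mapq)) stop("fragment records must carry a mapping quality in the score column")
  if (any(mapq < 0)) stop("negative mapping quality in ", path)
  frag <- GenomicRanges::granges(gr)
  frag$mapq <- as.integer(mapq)
  frag
}

#' Count fragment midpoints in regions
#'
#' Cell (i, s) is the number of sample-s fragments with mapping quality at
#' least \code{min_mapq} whose midpoint falls inside region i. Midpoint
#' assignment (rather than any-overlap) avoids double counting across
#' adjacent nucleosome-sized sub-peaks.
#'
#' @param fragments named list: one GRanges with a \code{mapq} column (or a
#'   BED6 file path) per sample
#' @param regions a \code{PeakSet}, or a GRanges with a \code{peak_id} column
#' @param min_mapq minimum mapping quality (default 10)
#' @param resolution resolution tag for the result (default \code{"broad"})
#' @param sampleMeta optional per-sample metadata data.frame
#' @return an \code{\link{EnrichmentMatrix}} of raw counts
#' @export
countFragments <- function(fragments, regions, min_mapq = 10,
                           resolution = "broad", sampleMeta = NULL) {
  if (min_mapq < 0) stop("min_mapq must be >= 0")
  gr <- if (methods::is(regions, "PeakSet")) peakRanges(regions) else regions
  if (length(gr) == 0) stop("regions must be non-empty")
  ids <- if (!is.null(gr$peak_id)) gr$peak_id else sprintf("region_%06d", seq_along(gr))
  if (is.null(names(fragments)))
    names(fragments) <- sprintf("sample_%02d", seq_along(fragments))
  counts <- vapply(fragments, function(fr) {
    fr <- .asFragments(fr)
    fr <- fr[fr$mapq >= min_mapq]
    GenomicRanges::countOverlaps(gr, .midpoints(fr), ignore.strand = TRUE)
  }, numeric(length(gr)))
  counts <- matrix(as.integer(counts), nrow = length(gr),
                   dimnames = list(ids, names(fragments)))
  EnrichmentMatrix(counts, resolution = resolution, sampleMeta = sampleMeta,
                   rowRanges = stats::setNames(gr, ids))
}

#' Median-of-ratios size factors
#'
#' DESeq-style normalization: for each sample, the size factor is the median
#' across regions (restricted to regions with all-positive counts) of the
#' ratio of that sample's count to the region's geometric mean across
#' samples. Factors are rescaled to geometric mean 1.
#'
#' @param counts an \code{EnrichmentMatrix} of raw counts, or a count matrix
#' @return named numeric vector of per-sample size factors (geometric mean 1)
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2)
#' sizeFactorsMedianRatio(m)  # (1/sqrt(2), sqrt(2))
#' @export
sizeFactorsMedianRatio <- function(counts) {
  k <- if (methods::is(counts, "EnrichmentMatrix")) enrichValues(counts) else as.matrix(counts)
  if (ncol(k) < 2) stop("need at least two samples")
  pos <- rowSums(k > 0) == ncol(k)
  if (!any(pos))
    stop("no region with all-positive counts; consider a pseudo-reference (e.g. add a pseudocount)")
  kp <- k[pos, , drop = FALSE]
  geo <- exp(rowMeans(log(kp)))
  sf <- apply(kp / geo, 2, stats::median)
  sf <- sf / geomMean(sf)
  stats::setNames(sf, colnames(k))
}

#' Log2 normalization of a count matrix
#'
#' value = log2(count / size_factor + pseudocount).
#'
#' @param counts an \code{EnrichmentMatrix} of raw counts
#' @param sizeFactors per-sample positive scalars; computed by
#'   \code{\link{sizeFactorsMedianRatio}} when NULL
#' @param pseudocount added before the log (default 1, so zero counts map to 0)
#' @return a normalized \code{EnrichmentMatrix} (assay \code{log2enrich})
#' @export
normalizeLog2 <- function(counts, sizeFactors = NULL, pseudocount = 1) {
  stopifnot(methods::is(counts, "EnrichmentMatrix"), !isNormalized(counts))
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianRatio(counts)
  if (any(sizeFactors <= 0)) stop("size factors must be positive")
  k <- enrichValues(counts)
  v <- log2(sweep(k, 2, sizeFactors, "/") + pseudocount)
  cd <- as.data.frame(SummarizedExperiment::colData(counts))
  EnrichmentMatrix(v, resolution = resolutionType(counts),
                   sampleMeta = if (ncol(cd)) cd else NULL,
                   normalized = TRUE, sizeFactors = unname(sizeFactors))
}

#' Aggregate nucleosome-resolution counts to broad peaks
#'
#' The raw broad-peak count is the sum of its constituent sub-peak counts.
#'
#' @param nucleosome an \code{EnrichmentMatrix} at nucleosome resolution
#' @param parentMap named character: sub-peak id -> parent broad peak id
#'   (e.g. \code{subpeakParent(peaks)})
#' @return an \code{EnrichmentMatrix} at broad resolution
#' @export
aggregateToBroad <- function(nucleosome, parentMap) {
  stopifnot(methods::is(nucleosome, "EnrichmentMatrix"), !isNormalized(nucleosome))
  ids <- regionIds(nucleosome)
  orphan <- setdiff(ids, names(parentMap))
  if (length(orphan))
    stop("sub-peaks without a parent: ", paste(utils::head(orphan, 3), collapse = ", "))
  parent <- parentMap[ids]
  agg <- rowsum(enrichValues(nucleosome), group = parent, reorder = TRUE)
  cd <- as.data.frame(SummarizedExperiment::colData(nucleosome))
  EnrichmentMatrix(agg, resolution = "broad",
                   sampleMeta = if (ncol(cd)) cd else NULL)
}

#' TSS metaprofile of fragment density
#'
#' Each fragment midpoint within \code{half_window} of a TSS is assigned to
#' its nearest TSS; the strand-oriented signed distance is binned. Per-sample
#' bin counts are normalized by that sample's total fragments within the TSS
#' windows (bin masses sum to 1 per sample), then averaged within groups.
#'
#' @param fragments named list of fragment GRanges (or BED6 paths), one per sample
#' @param tss GRanges of TSS positions
#' @param half_window half-width of the profiled window (default 2000)
#' @param bin bin width in bases; must divide \code{2 * half_window}
#' @param groups character/factor of group labels, one per sample
#' @param min_mapq minimum mapping quality (default 10)
#' @return list with \code{profile} (group x bin matrix of mean mass) and
#'   \code{bin_mid} (signed distances of bin centres from the TSS)
#' @export
tssMetaprofile <- function(fragments, tss, half_window = 2000, bin = 50,
                           groups, min_mapq = 10) {
  if ((2 * half_window) %% bin != 0) stop("bin must divide 2 * half_window")
  if (is.null(names(fragments)))
    names(fragments) <- sprintf("sample_%02d", seq_along(fragments))
  groups <- as.factor(groups)
  if (length(groups) != length(fragments)) stop("one group label per sample required")
  if (any(table(groups) == 0)) stop("empty group")
  nbins <- as.integer(2 * half_window / bin)
  win <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(tss),
                                IRanges::IRanges(pmax(1L, GenomicRanges::start(tss) - half_window),
                                                 GenomicRanges::start(tss) + half_window - 1L))
  sampleMass <- matrix(0, nrow = length(fragments), ncol = nbins,
                       dimnames = list(names(fragments), NULL))
  tssStrand <- as.character(GenomicRanges::strand(tss))
  tssPos <- GenomicRanges::start(tss)
  for (s in seq_along(fragments)) {
    fr <- .asFragments(fragments[[s]])
    fr <- fr[fr$mapq >= min_mapq]
    mid <- .midpoints(fr)
    hits <- GenomicRanges::findOverlaps(mid, win, ignore.strand = TRUE)
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    d <- GenomicRanges::start(mid)[qh] - tssPos[sh]
    ## nearest TSS per fragment; ties to the first TSS in input order
    o <- order(qh, abs(d), sh)
    firsts <- !duplicated(qh[o])
    qh <- qh[o][firsts]; sh <- sh[o][firsts]; d <- d[o][firsts]
    ## half-open mirror for minus-strand genes: base at +k maps to -k-1,
    ## so the reflected offsets stay in [-hw, hw) and bins mirror exactly
    d <- ifelse(tssStrand[sh] == "-", -d - 1L, d)
    idx <- pmin(nbins, pmax(1L, floor((d + half_window) / bin) + 1L))
    tab <- tabulate(idx, nbins)
    sampleMass[s, ] <- tab / sum(tab)
  }
  grp <- as.character(groups)
  agg <- rowsum(sampleMass, group = grp, reorder = TRUE)
  prof <- agg / as.vector(table(grp)[rownames(agg)])
  binMid <- seq(-half_window + bin / 2, half_window - bin / 2, by = bin)
  list(profile = prof, bin_mid = binMid)
}
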