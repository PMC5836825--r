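## Window-based differential enrichment (csaw-style alternative workflow).

#' Tile a genome into fixed-width windows
#'
#' @param seqlengths named integer vector of chromosome lengths
#' @param width window width in bases (default 150)
#' @return GRanges of non-overlapping windows with \code{peak_id} labels
#' @export
tileWindows <- function(seqlengths, width = 150) {
  grl <- lapply(names(seqlengths), function(chr) {
    len <- seqlengths[[chr]]
    starts <- seq(1L, len, by = width)
    GenomicRanges::GRanges(chr, IRanges::IRanges(starts, pmin(starts + width - 1L, len)))
  })
  gr <- do.call(c, grl)
  gr$peak_id <- sprintf("win_%07d", seq_along(gr))
  gr
}

#' Window-based differential enrichment workflow
#'
#' Tiles the genome into non-overlapping \code{window}-bp windows, counts
#' fragment midpoints with mapping quality >= \code{min_mapq}, keeps windows
#' whose average depth-scaled abundance is at least \code{global_fold} times
#' the global background (the median abundance of \code{bg_bin}-bp bins,
#' rescaled to window width), normalizes retained windows for
#' efficiency/composition bias with TMM factors, runs the NB Wald test per
#' window and contrast, clusters retained windows into candidate regions
#' (gap at most one window), combines window p-values per region with Simes'
#' method, and applies BH across regions at \code{fdr}.
#'
#' @param fragments named list of fragment GRanges (or BED6 paths), one per
#'   sample
#' @param group group labels, one per sample
#' @param seqlengths named chromosome lengths for tiling
#' @param contrasts list of length-2 contrasts (default HD and MS vs CTRL)
#' @param window window width (default 150)
#' @param global_fold abundance filter multiple (default 5)
#' @param fdr region-level FDR (default 0.10)
#' @param min_mapq minimum mapping quality (default 10)
#' @param bg_bin background bin width (default 2000)
#' @param blacklist optional GRanges excluded from tiling
#' @return a \code{DataFrame} of candidate regions per contrast: coordinates,
#'   n_windows, log2fc (of the best window), pvalue (Simes), qvalue,
#'   significant; window counts and the retained-window ids are in
#'   \code{metadata}
#' @export
windowWorkflow <- function(fragments, group, seqlengths,
                           contrasts = list(c("HD", "CTRL"), c("MS", "CTRL")),
                           window = 150, global_fold = 5.0, fdr = 0.10,
                           min_mapq = 10, bg_bin = 2000, blacklist = NULL) {
  wins <- tileWindows(seqlengths, window)
  if (!is.null(blacklist) && length(blacklist))
    wins <- wins[GenomicRanges::countOverlaps(wins, blacklist) == 0]
  frags <- lapply(fragments, .asFragments)
  em <- countFragments(frags, wins, min_mapq = min_mapq, resolution = "window")
  k <- enrichValues(em)
  lib <- colSums(k)
  depthScale <- lib / mean(lib)
  kn <- sweep(k, 2, depthScale, "/")
  ab <- rowMeans(kn)
  ## global background: median abundance of large bins, rescaled to windows
  bins <- tileWindows(seqlengths, bg_bin)
  if (!is.null(blacklist) && length(blacklist))
    bins <- bins[GenomicRanges::countOverlaps(bins, blacklist) == 0]
  bk <- enrichValues(countFragments(frags, bins, min_mapq = min_mapq,
                                    resolution = "window"))
  bgAb <- stats::median(rowMeans(sweep(bk, 2, depthScale, "/"))) * window / bg_bin
  retained <- ab >= global_fold * max(bgAb, .Machine$double.eps)
  if (!any(retained)) stop("no windows pass abundance filter")
  kr <- k[retained, , drop = FALSE]
  wr <- wins[retained]
  ## efficiency-bias normalization: TMM on retained windows
  nf <- edgeR::calcNormFactors(kr, lib.size = lib)
  sf <- lib * nf
  sf <- sf / geomMean(sf)
  disp <- estimateDispersions(kr, group, sf)
  ## candidate regions: retained windows merged across gaps <= 1 window
  merged <- GenomicRanges::reduce(wr, min.gapwidth = window + 1L)
  ov <- GenomicRanges::findOverlaps(wr, merged)
  regIdx <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
  simes <- function(p) {
    p <- p[!is.na(p)]
    if (!length(p)) return(NA_real_)
    m <- length(p)
    min(1, min(m * sort(p) / seq_len(m)))
  }
  res <- lapply(contrasts, function(ct) {
    tt <- nbWaldTest(kr, group, ct, sizeFactors = sf, dispersions = disp)
    regFac <- factor(regIdx, levels = seq_along(merged))
    pReg <- vapply(split(tt$pvalue, regFac), simes, numeric(1))
    lfcReg <- vapply(split(seq_len(nrow(tt)), regFac), function(ix) {
      pv <- tt$pvalue[ix]
      if (all(is.na(pv))) return(NA_real_)
      tt$log2fc[ix][which.min(pv)]
    }, numeric(1))
    nw <- as.vector(table(factor(regIdx, levels = seq_along(merged))))
    q <- bhAdjust(pReg)
    S4Vectors::DataFrame(chrom = as.character(GenomeInfoDb::seqnames(merged)),
                         start = GenomicRanges::start(merged) - 1L,
                         end = GenomicRanges::end(merged),
                         n_windows = nw,
                         contrast = paste(ct, collapse = "_vs_"),
                         log2fc = lfcReg, pvalue = pReg, qvalue = q,
                         significant = !is.na(q) & q <= fdr)
  })
  out <- do.call(rbind, res)
  S4Vectors::metadata(out)$n_retained_windows <- sum(retained)
  S4Vectors::metadata(out)$background_abundance <- bgAb
  S4Vectors::metadata(out)$thresholds <- list(window = window,
                                              global_fold = global_fold,
                                              fdr = fdr, min_mapq = min_mapq)
  out
}
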