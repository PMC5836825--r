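## Small internal helpers shared across modules.

#' Geometric mean
#'
#' @param x numeric vector, all positive
#' @param na.rm drop NA values first
#' @return the geometric mean of \code{x}
#' @keywords internal
geomMean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  exp(mean(log(x)))
}

## Midpoints of ranges as width-1 GRanges (floor of the arithmetic mean,
## matching the half-open-interval midpoint used at the I/O boundary).
.midpoints <- function(gr) {
  mid <- floor((GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2)
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                         IRanges::IRanges(mid, width = 1L),
                         strand = GenomicRanges::strand(gr))
}

.assertScalarNumber <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

## Shared-chromosome sanity check: catches "chr1" vs "1" style mismatches.
.checkSharedSeqnames <- function(a, b, what = c("peaks", "annotation")) {
  sa <- as.character(unique(GenomeInfoDb::seqnames(a)))
  sb <- as.character(unique(GenomeInfoDb::seqnames(b)))
  if (length(sa) && length(sb) && !length(intersect(sa, sb)))
    stop(sprintf(paste0("no chromosome names shared between %s (%s...) and %s ",
                        "(%s...); harmonize naming (e.g. strip 'chr') before calling"),
                 what[1], sa[1], what[2], sb[1]), call. = FALSE)
  invisible(NULL)
}

## Extract a plain fragment GRanges with an integer mapq metadata column from
## the accepted fragment representations (GRanges, or a BED6 file path).
.asFragments <- function(x) {
  if (methods::is(x, "GRanges")) {
    if (is.null(x$mapq)) stop("fragment GRanges must carry a 'mapq' metadata column")
    return(x)
  }
  if (is.character(x) && length(x) == 1L) return(readFragments(x))
  stop("fragments must be a GRanges with a 'mapq' column or a BED6 file path")
}
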