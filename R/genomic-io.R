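## Peak / annotation I/O and promoter-centred interval logic.
##
## Internally all coordinates are GRanges (1-based, closed). BED-style inputs
## (0-based, half-open) are converted on read and back on write, so the
## on-disk convention round-trips exactly.

.dialectCols <- c(bed = 3L, broadPeak = 9L, narrowPeak = 10L)

#' Read peak intervals (BED / MACS broadPeak / narrowPeak)
#'
#' Parses a peak file into a \code{\link{PeakSet}}. For the ENCODE dialects,
#' column 9 holds -log10(q); it is converted to a q-value (an ENCODE sentinel
#' of -1 becomes NA). Malformed lines raise an error naming the line number;
#' intervals with start >= end are rejected.
#'
#' @param path path to the peak file
#' @param dialect one of \code{"bed"} (3-6 columns), \code{"broadPeak"} (9),
#'   \code{"narrowPeak"} (10)
#' @return a \code{\link{PeakSet}}
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t300", f)
#' readIntervals(f, "bed")
#' @export
readIntervals <- function(path, dialect = c("bed", "broadPeak", "narrowPeak")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines)) stop("no interval records in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  need <- .dialectCols[[dialect]]
  bad <- if (dialect == "bed") which(nf < 3L) else which(nf < need)
  if (length(bad))
    stop(sprintf("parse error at line %d of %s: expected >= %d tab-separated columns, found %d",
                 bad[1], path, need, nf[bad[1]]))
  getcol <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_,
                               character(1))
  chrom <- getcol(1)
  start0 <- suppressWarnings(as.numeric(getcol(2)))
  end0 <- suppressWarnings(as.numeric(getcol(3)))
  badnum <- which(is.na(start0) | is.na(end0))
  if (length(badnum))
    stop(sprintf("parse error at line %d of %s: non-numeric coordinates", badnum[1], path))
  badiv <- which(start0 >= end0 | start0 < 0)
  if (length(badiv))
    stop(sprintf("invalid interval at line %d of %s: need 0 <= start < end (got %g, %g)",
                 badiv[1], path, start0[badiv[1]], end0[badiv[1]]))
  n <- length(lines)
  name <- if (max(nf) >= 4L) getcol(4) else sprintf("peak_%06d", seq_len(n))
  name[is.na(name) | name == "."] <- sprintf("peak_%06d", seq_len(n))[is.na(name) | name == "."]
  score <- if (max(nf) >= 5L) suppressWarnings(as.numeric(getcol(5))) else rep(NA_real_, n)
  strand <- if (max(nf) >= 6L) getcol(6) else rep(".", n)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "*"
  strand[strand == "."] <- "*"
  q <- rep(NA_real_, n)
  if (dialect %in% c("broadPeak", "narrowPeak")) {
    ml10q <- suppressWarnings(as.numeric(getcol(9)))
    q <- ifelse(!is.na(ml10q) & ml10q >= 0, 10^(-ml10q), NA_real_)
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0),
                               strand = strand)
  gr$peak_id <- make.unique(name, sep = "_")
  gr$score <- score
  gr$q_value <- q
  PeakSet(gr)
}

#' Write peak intervals as BED6
#'
#' Coordinates are written 0-based half-open; \code{readIntervals} on the
#' output reproduces them exactly.
#'
#' @param x a \code{PeakSet} or GRanges
#' @param path output path
#' @return invisibly, the path
#' @export
writeIntervalsBed <- function(x, path) {
  gr <- if (methods::is(x, "PeakSet")) peakRanges(x) else x
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  score <- if (is.null(gr$score)) rep(0, length(gr)) else ifelse(is.na(gr$score), 0, gr$score)
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = if (is.null(gr$peak_id)) "." else gr$peak_id,
                   score = score, strand = strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Import a GTF/GFF gene annotation
#'
#' Thin wrapper over \code{rtracklayer::import} returning the annotation
#' GRanges (GENCODE attribute dialect expected: \code{type}, \code{gene_id},
#' optionally \code{gene_name}).
#'
#' @param path GTF file path
#' @return GRanges of annotation features
#' @export
importAnnotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  rtracklayer::import(path)
}

## Transcription start sites from an annotation GRanges: feature start for +
## strand, feature end for - strand, collapsed to unique (gene_id, position).
.tssFromAnnotation <- function(ann) {
  if (is.null(ann$gene_id) || anyNA(ann$gene_id))
    stop("annotation features must carry a gene_id attribute")
  keep <- if (!is.null(ann$type) && any(ann$type == "transcript"))
    ann[ann$type == "transcript"]
  else if (!is.null(ann$type) && any(ann$type == "gene"))
    ann[ann$type == "gene"]
  else ann
  str <- as.character(GenomicRanges::strand(keep))
  if (any(!str %in% c("+", "-")))
    stop("annotation features must have '+' or '-' strand for TSS derivation")
  pos <- ifelse(str == "+", GenomicRanges::start(keep), GenomicRanges::end(keep))
  key <- paste(keep$gene_id, as.character(GenomeInfoDb::seqnames(keep)), pos)
  first <- !duplicated(key)
  tss <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(keep)[first],
                                IRanges::IRanges(pos[first], width = 1L),
                                strand = str[first])
  tss$gene_id <- keep$gene_id[first]
  tss$gene_name <- if (!is.null(keep$gene_name)) keep$gene_name[first] else keep$gene_id[first]
  tss
}

#' Read transcription start sites from a GTF annotation
#'
#' The TSS is the feature start on the + strand and the feature end on the -
#' strand; transcripts sharing a (gene, position) collapse to one record.
#'
#' @param path GTF file path
#' @return GRanges of width-1 TSS positions with mcols \code{gene_id},
#'   \code{gene_name}
#' @export
readTss <- function(path) .tssFromAnnotation(importAnnotation(path))

#' Promoter windows around TSS positions
#'
#' Each promoter spans \code{flank} bases on either side of the TSS
#' (a window of width \code{2 * flank}), clamped at the chromosome start;
#' strand is preserved.
#'
#' @param tss GRanges of width-1 TSS positions (from \code{\link{readTss}})
#' @param flank half-width in bases (default 1000, i.e. +/- 1 kb)
#' @return GRanges of promoter windows (mcols carried over from \code{tss})
#' @export
promoterRegions <- function(tss, flank = 1000) {
  .assertScalarNumber(flank, "flank", positive = TRUE)
  pos <- GenomicRanges::start(tss)
  prom <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(tss),
                                 IRanges::IRanges(pmax(1L, as.integer(pos - flank)),
                                                  as.integer(pos + flank - 1L)),
                                 strand = GenomicRanges::strand(tss))
  S4Vectors::mcols(prom) <- S4Vectors::mcols(tss)
  prom
}

#' Assign peaks to promoters and the nearest gene
#'
#' Records, for every peak, all genes whose promoter window (+/- \code{flank}
#' around the TSS) overlaps the peak by at least one base; flags peaks whose
#' assigned genes include TSSs on both strands as bidirectional-promoter
#' peaks; and records the nearest gene by peak-midpoint-to-TSS distance
#' (ties broken by lexicographic gene id).
#'
#' @param peaks a \code{PeakSet}
#' @param tss GRanges of TSS records (\code{\link{readTss}})
#' @param flank promoter half-width in bases (default 1000)
#' @return the \code{PeakSet} with annotation slots filled
#' @export
assignPeaks <- function(peaks, tss, flank = 1000) {
  if (length(tss) == 0) stop("TSS list is empty")
  gr <- peakRanges(peaks)
  .checkSharedSeqnames(gr, tss, c("peaks", "TSS records"))
  prom <- promoterRegions(tss, flank)
  hits <- GenomicRanges::findOverlaps(gr, prom, ignore.strand = TRUE)
  ids <- gr$peak_id
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  geneIdVec <- tss$gene_id
  strandVec <- as.character(GenomicRanges::strand(tss))
  ga <- stats::setNames(vector("list", length(gr)), ids)
  ga[] <- list(character(0))
  bidir <- stats::setNames(rep(FALSE, length(gr)), ids)
  if (length(hits)) {
    byPeak <- split(seq_along(qh), qh)
    idx <- as.integer(names(byPeak))
    ga[idx] <- lapply(byPeak, function(h) sort(unique(geneIdVec[sh[h]])))
    bidir[idx] <- vapply(byPeak, function(h) {
      str <- strandVec[sh[h]]
      length(unique(geneIdVec[sh[h]])) >= 2 && any(str == "+") && any(str == "-")
    }, logical(1))
  }
  ## nearest gene by midpoint-to-TSS distance, lexicographic gene_id tie-break
  mid <- .midpoints(gr)
  near <- stats::setNames(rep(NA_character_, length(gr)), ids)
  dn <- GenomicRanges::distanceToNearest(mid, tss, select = "all",
                                         ignore.strand = TRUE)
  if (length(dn)) {
    qn <- S4Vectors::queryHits(dn)
    gid <- geneIdVec[S4Vectors::subjectHits(dn)]
    byPeak <- split(gid, qn)
    near[as.integer(names(byPeak))] <- vapply(byPeak, min, character(1))
  }
  methods::new("PeakSet", peaks = gr, subpeakParent = subpeakParent(peaks),
               geneAssignments = ga, nearestGene = near, bidirectional = bidir)
}

#' Classify peaks by genomic context
#'
#' Decides each peak's context at its midpoint with precedence
#' promoter > exon > intron > intergenic. Promoter windows are +/-
#' \code{flank} around every TSS; intron means inside a gene body but not in
#' an exon or promoter.
#'
#' @param peaks a \code{PeakSet}
#' @param annotation annotation GRanges (\code{\link{importAnnotation}}) with
#'   \code{type} values including \code{exon} (and \code{gene} or
#'   \code{transcript} for gene bodies)
#' @param flank promoter half-width (default 1000)
#' @return list with \code{context} (named character per peak) and
#'   \code{proportions} (named numeric over the four categories)
#' @export
classifyContext <- function(peaks, annotation, flank = 1000) {
  gr <- peakRanges(peaks)
  mid <- .midpoints(gr)
  tss <- .tssFromAnnotation(annotation)
  prom <- promoterRegions(tss, flank)
  if (is.null(annotation$type) || !any(annotation$type == "exon"))
    stop("annotation must include exon features")
  exons <- annotation[annotation$type == "exon"]
  bodies <- if (any(annotation$type == "gene")) annotation[annotation$type == "gene"]
            else annotation[annotation$type == "transcript"]
  ctx <- rep("intergenic", length(gr))
  inProm <- GenomicRanges::countOverlaps(mid, prom, ignore.strand = TRUE) > 0
  inExon <- GenomicRanges::countOverlaps(mid, exons, ignore.strand = TRUE) > 0
  inBody <- GenomicRanges::countOverlaps(mid, bodies, ignore.strand = TRUE) > 0
  ctx[inBody] <- "intron"
  ctx[inExon] <- "exon"
  ctx[inProm] <- "promoter"
  ctx <- stats::setNames(ctx, gr$peak_id)
  lev <- c("promoter", "exon", "intron", "intergenic")
  prop <- table(factor(ctx, levels = lev)) / length(ctx)
  list(context = ctx, proportions = stats::setNames(as.numeric(prop), lev))
}

#' Remove peaks overlapping blacklist regions
#'
#' Peaks overlapping any blacklist interval by at least one base are dropped
#' (half-open BED semantics apply on read, so an interval abutting a
#' blacklist region is kept). Sub-peaks of removed broad peaks are removed
#' with their parent.
#'
#' @param peaks a \code{PeakSet}
#' @param blacklist GRanges of excluded regions (may be empty)
#' @return the filtered \code{PeakSet}; the number removed is reported via
#'   \code{message}
#' @export
subtractBlacklist <- function(peaks, blacklist) {
  gr <- peakRanges(peaks)
  if (length(blacklist) == 0) return(peaks)
  drop <- GenomicRanges::countOverlaps(gr, blacklist, ignore.strand = TRUE) > 0
  dropIds <- gr$peak_id[drop]
  sp <- subpeakParent(peaks)
  orphaned <- names(sp)[sp %in% dropIds]
  dropIds <- union(dropIds, orphaned)
  keep <- !(gr$peak_id %in% dropIds)
  message(sprintf("subtractBlacklist: removed %d of %d peaks", sum(!keep), length(gr)))
  keepIds <- gr$peak_id[keep]
  sp <- sp[names(sp) %in% keepIds & sp %in% keepIds]
  ga <- geneAssignments(peaks)
  ng <- nearestGene(peaks)
  bd <- isBidirectional(peaks)
  methods::new("PeakSet", peaks = gr[keep], subpeakParent = sp,
               geneAssignments = ga[names(ga) %in% keepIds],
               nearestGene = ng[names(ng) %in% keepIds],
               bidirectional = bd[names(bd) %in% keepIds])
}

#' Write an annotated peak table
#'
#' TSV with peak id, BED-style coordinates, score, q-value, assigned genes
#' (comma-separated), nearest gene, bidirectional flag and (optionally)
#' genomic context.
#'
#' @param peaks an annotated \code{PeakSet}
#' @param path output path
#' @param context optional named context vector from \code{\link{classifyContext}}
#' @return invisibly, the written data.frame
#' @export
writeAnnotatedPeaks <- function(peaks, path, context = NULL) {
  gr <- peakRanges(peaks)
  ids <- gr$peak_id
  ga <- geneAssignments(peaks)
  genes <- vapply(ids, function(i)
    paste(if (i %in% names(ga)) ga[[i]] else character(0), collapse = ","),
    character(1))
  df <- data.frame(peak_id = ids,
                   chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   score = gr$score, q_value = gr$q_value,
                   genes = genes,
                   nearest_gene = unname(nearestGene(peaks)[ids]),
                   bidirectional = unname(isBidirectional(peaks)[ids]))
  if (!is.null(context)) df$context <- unname(context[ids])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
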