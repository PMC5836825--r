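## Fixture builders shared across test files. Everything is generated in
## code; no binary or downloaded data.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

## a tiny GTF written as plain text (1-based inclusive coordinates)
writeTinyGtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtfLine <- function(chrom, type, start, end, strand, gene_id,
                    gene_name = gene_id) {
  sprintf(paste0('%s\tsynthetic\t%s\t%d\t%d\t.\t%s\t.\t',
                 'gene_id "%s"; gene_name "%s";'),
          chrom, type, start, end, strand, gene_id, gene_name)
}

## PeakSet from 0-based half-open coordinate triples
peaksFrom0Based <- function(chrom, start0, end0, ids = NULL) {
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
  gr$peak_id <- if (is.null(ids)) sprintf("pk%03d", seq_along(gr)) else ids
  PeakSet(gr)
}

## width-1 TSS GRanges at 0-based positions
tssAt0Based <- function(pos0, strand = "+", gene_id = NULL, chrom = "chr1") {
  gr <- GRanges(chrom, IRanges(pos0 + 1L, width = 1L), strand = strand)
  gr$gene_id <- if (is.null(gene_id)) sprintf("g%03d", seq_along(gr)) else gene_id
  gr$gene_name <- gr$gene_id
  gr
}

## fragments with given 0-based midpoints and mapq values
fragsAtMidpoints <- function(mid0, mapq = 30, chrom = "chr1", halfwidth = 73) {
  gr <- GRanges(chrom, IRanges(pmax(1L, mid0 + 1L - halfwidth), mid0 + 1L + halfwidth))
  gr$mapq <- as.integer(rep_len(mapq, length(gr)))
  gr
}

## NB count matrix with row/col names
nbMatrix <- function(n, s, mu, alpha, seed) {
  set.seed(seed)
  k <- matrix(rnbinom(n * s, mu = mu, size = 1 / alpha), n, s)
  dimnames(k) <- list(sprintf("r%05d", seq_len(n)), sprintf("s%02d", seq_len(s)))
  k
}

## small default-structure simulation (keeps module tests fast)
smallSim <- function(seed, ...) {
  args <- list(seed = seed, n_genes = 400, n_broad_peaks = 300,
               depth = 4e4, n_cluster_regions = 15, n_de_regions = 10,
               input_bias_regions = 5)
  dots <- list(...)
  args[names(dots)] <- dots
  cfg <- do.call(simConfig, args)
  ann <- simulateAnnotation(cfg)
  sim <- simulateCounts(cfg, ann)
  list(cfg = cfg, ann = ann, sim = sim)
}
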