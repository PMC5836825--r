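test_that("readIntervals parses BED and ENCODE peak dialects with validation", {
  f <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t300", f)
  ps <- readIntervals(f, "bed")
  gr <- peakRanges(ps)
  expect_equal(start(gr), 101L)  # 0-based 100 -> 1-based 101
  expect_equal(end(gr), 300L)

  ## broadPeak: column 9 is -log10(q)
  bp <- tempfile(fileext = ".broadPeak")
  writeLines(paste(c("chr1", 100, 300, "pkA", 50, ".", 4.2, 3.0, 2.0),
                   collapse = "\t"), bp)
  ps <- readIntervals(bp, "broadPeak")
  expect_equal(peakRanges(ps)$q_value, 0.01)

  ## start >= end rejected with the line number
  np <- tempfile(fileext = ".narrowPeak")
  writeLines(c(paste(c("chr1", 100, 300, "a", 0, ".", 1, 2, 2, 50), collapse = "\t"),
               paste(c("chr1", 500, 500, "b", 0, ".", 1, 2, 2, 50), collapse = "\t")),
             np)
  expect_error(readIntervals(np, "narrowPeak"), "line 2")

  ## short line rejected with the line number
  bad <- tempfile()
  writeLines(c("chr1\t1\t10", "chr1\t5"), bad)
  expect_error(readIntervals(bad, "bed"), "line 2")
})

test_that("BED write/read round trip preserves coordinates exactly", {
  set.seed(42)
  s0 <- sort(sample(1e6, 50))
  ps <- peaksFrom0Based("chr2", s0, s0 + sample(50:2000, 50, replace = TRUE))
  f <- tempfile(fileext = ".bed")
  writeIntervalsBed(ps, f)
  ps2 <- readIntervals(f, "bed")
  expect_equal(start(peakRanges(ps2)), start(peakRanges(ps)))
  expect_equal(end(peakRanges(ps2)), end(peakRanges(ps)))
  expect_equal(peakRanges(ps2)$peak_id, peakRanges(ps)$peak_id)
})

test_that("readTss applies the strand convention and deduplicates", {
  ## gene on [1000, 2000) 0-based = 1001..2000 1-based
  f <- writeTinyGtf(c(
    gtfLine("chr1", "transcript", 1001, 2000, "+", "gPlus"),
    gtfLine("chr1", "transcript", 1001, 2000, "-", "gMinus"),
    gtfLine("chr1", "transcript", 1001, 1500, "+", "gPlus")))  # same TSS
  tss <- readTss(f)
  plus <- tss[tss$gene_id == "gPlus"]
  minus <- tss[tss$gene_id == "gMinus"]
  expect_equal(start(plus) - 1L, 1000L)   # tss (0-based) = start
  expect_equal(start(minus) - 1L, 1999L)  # tss (0-based) = end - 1
  expect_length(plus, 1)                  # two transcripts, one record
})

test_that("promoterRegions spans +/- flank with clamping, rejects flank <= 0", {
  tss <- tssAt0Based(c(5000, 400))
  prom <- promoterRegions(tss, flank = 1000)
  ## [4000, 6000) 0-based
  expect_equal(start(prom)[1] - 1L, 4000L)
  expect_equal(end(prom)[1], 6000L)
  ## clamped at chromosome start: [0, 1400)
  expect_equal(start(prom)[2], 1L)
  expect_equal(end(prom)[2], 1400L)
  expect_error(promoterRegions(tss, flank = 0))
})

test_that("assignPeaks records overlapping genes, nearest gene, bidirectionality", {
  tss <- c(tssAt0Based(5000, "+", "gA"),
           tssAt0Based(5200, "-", "gB"),
           tssAt0Based(50000, "+", "gFar"))
  ps <- peaksFrom0Based("chr1", c(4900, 4900, 20000), c(5100, 5400, 20100),
                        ids = c("near", "divergent", "orphan"))
  ann <- assignPeaks(ps, tss, flank = 1000)
  ga <- geneAssignments(ann)
  expect_setequal(ga[["near"]], c("gA", "gB"))
  expect_true(isBidirectional(ann)[["divergent"]])
  expect_length(ga[["orphan"]], 0)
  expect_false(isBidirectional(ann)[["orphan"]])
  expect_equal(nearestGene(ann)[["near"]], "gA")

  ## invariance to input ordering and idempotence
  ann2 <- assignPeaks(assignPeaks(ps, rev(tss)), tss)
  expect_equal(geneAssignments(ann2), ga)
  expect_equal(isBidirectional(ann2), isBidirectional(ann))

  ## bidirectional always implies >= 2 genes
  bd <- isBidirectional(ann)
  for (id in names(bd)[bd]) expect_gte(length(ga[[id]]), 2)

  expect_error(assignPeaks(ps, tss[0]), "empty")
})

test_that("classifyContext applies promoter > exon > intron > intergenic at midpoints", {
  f <- writeTinyGtf(c(
    gtfLine("chr1", "gene", 10001, 20000, "+", "g1"),
    gtfLine("chr1", "exon", 10001, 10400, "+", "g1"),
    gtfLine("chr1", "exon", 19500, 20000, "+", "g1")))
  ann <- importAnnotation(f)
  ps <- peaksFrom0Based("chr1", c(9900, 14000, 19600, 40000),
                        c(10100, 14200, 19800, 40200),
                        ids = c("prom", "intron", "exon", "inter"))
  ctx <- classifyContext(ps, ann, flank = 1000)
  expect_equal(unname(ctx$context[c("prom", "intron", "exon", "inter")]),
               c("promoter", "intron", "exon", "intergenic"))
  expect_equal(sum(ctx$proportions), 1)
})

test_that("classifyContext recovers the planted promoter fraction on synthetic data", {
  sm <- smallSim(31)
  ctx <- classifyContext(sm$sim$peaks, sm$ann$annotation)
  ## 90% of peaks planted at promoters; binomial error at n = 300 broad peaks
  expect_gt(ctx$proportions[["promoter"]], 0.84)
  expect_lt(ctx$proportions[["promoter"]], 0.96)
})

test_that("subtractBlacklist removes any-overlap peaks, keeps abutting ones", {
  ps <- peaksFrom0Based("chr1", c(100, 100, 1000), c(200, 200, 1100),
                        ids = c("hit", "hit2", "kept"))
  ps <- peaksFrom0Based("chr1", c(100, 1000), c(200, 1100), ids = c("hit", "kept"))
  bl <- GRanges("chr1", IRanges(151, 160))           # 0-based [150,160) overlaps
  bl2 <- GRanges("chr1", IRanges(201, 300))          # 0-based [200,300) abuts
  expect_message(out <- subtractBlacklist(ps, c(bl, bl2)), "removed 1")
  expect_equal(peakIds(out), "kept")
  ## empty blacklist is the identity
  expect_equal(peakIds(subtractBlacklist(ps, GRanges())), peakIds(ps))
  ## property: output subset of input, no residual overlap (brute force)
  set.seed(5)
  big <- peaksFrom0Based("chr1", s <- sample(1e5, 60), s + 500)
  blr <- GRanges("chr1", IRanges(sample(1e5, 10), width = 800))
  suppressMessages(filt <- subtractBlacklist(big, blr))
  expect_true(all(peakIds(filt) %in% peakIds(big)))
  for (i in seq_along(peakRanges(filt)))
    expect_equal(countOverlaps(peakRanges(filt)[i], blr), 0L)
})

test_that("mismatched chromosome naming is an error, not silent harmonization", {
  ps <- peaksFrom0Based("1", 100, 300)
  tss <- tssAt0Based(200, chrom = "chr1")
  expect_error(assignPeaks(ps, tss), "chromosome")
})

test_that("PeakSet validity enforces sub-peak containment and q range", {
  gr <- GRanges("chr1", IRanges(c(101, 121), c(200, 250)))
  gr$peak_id <- c("parent", "child")
  expect_error(PeakSet(gr, subpeakParent = c(child = "parent")), "within")
  gr2 <- GRanges("chr1", IRanges(101, 200))
  gr2$peak_id <- "p"; gr2$q_value <- 1.5
  expect_error(PeakSet(gr2), "q_value")
})
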