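## helper: build a long-format Ct table from named vectors
ctRows <- function(sample_id, target, fraction, ct, replicate = 1) {
  data.frame(sample_id = sample_id, target = target, fraction = fraction,
             replicate = replicate, ct = ct)
}

test_that("foldEnrichment follows the 2^dCt ratio with the FE > 25 gate", {
  ## dCt_pos = 6, dCt_neg = 1 -> FE = 2^6 / 2^1 = 32
  ct <- rbind(ctRows("s1", "pos", "input", 25), ctRows("s1", "pos", "IP", 19),
              ctRows("s1", "neg", "input", 26), ctRows("s1", "neg", "IP", 25))
  fe <- foldEnrichment(ct, "pos", "neg")
  expect_equal(fe$fe, 32)
  expect_true(fe$pass)
  ## equal dCt -> FE = 1, fails the gate
  ct2 <- rbind(ctRows("s1", "pos", "input", 25), ctRows("s1", "pos", "IP", 24),
               ctRows("s1", "neg", "input", 26), ctRows("s1", "neg", "IP", 25))
  fe2 <- foldEnrichment(ct2, "pos", "neg")
  expect_equal(fe2$fe, 1)
  expect_false(fe2$pass)
  ## invariant to adding a constant to all Ct values
  ct3 <- ct; ct3$ct <- ct3$ct + 3.7
  expect_equal(foldEnrichment(ct3, "pos", "neg")$fe, 32)
  ## replicates averaged before differencing, order-invariant
  ct4 <- rbind(ctRows("s1", "pos", "input", c(25, 26), replicate = 1:2),
               ctRows("s1", "pos", "IP", c(19, 20), replicate = 1:2),
               ctRows("s1", "neg", "input", 26), ctRows("s1", "neg", "IP", 25))
  expect_equal(foldEnrichment(ct4, "pos", "neg")$fe,
               foldEnrichment(ct4[sample(nrow(ct4)), ], "pos", "neg")$fe)
  ## missing fraction errors with the sample and locus named
  expect_error(foldEnrichment(ct[-2, ], "pos", "neg"), "s1.*pos")
})

test_that("genormStability scores parallel genes as perfectly stable", {
  samples <- paste0("s", 1:6)
  base <- rnorm(6, 22, 1)
  ct <- rbind(ctRows(samples, "hk1", "cDNA", base),
              ctRows(samples, "hk2", "cDNA", base + 2))  # constant offset
  st <- genormStability(ct, c("hk1", "hk2"))
  expect_equal(unname(st$M), c(0, 0))
  expect_true(st$pass)
  ## two-gene M is symmetric by construction
  ct2 <- rbind(ctRows(samples, "hk1", "cDNA", base),
               ctRows(samples, "hk2", "cDNA", base + rnorm(6, 0, 0.3)))
  st2 <- genormStability(ct2, c("hk1", "hk2"))
  expect_equal(st2$M[["hk1"]], st2$M[["hk2"]])
  expect_error(genormStability(ct, "hk1"), "2 candidate")
})

test_that("genorm M matches a direct-formula oracle and grows with noise", {
  set.seed(12)
  samples <- paste0("s", 1:6)
  wide <- matrix(rnorm(18, 21, 1.2), 6, 3,
                 dimnames = list(samples, c("g1", "g2", "g3")))
  ct <- do.call(rbind, lapply(colnames(wide), function(g)
    ctRows(samples, g, "cDNA", wide[, g])))
  st <- genormStability(ct, colnames(wide), M_max = Inf, CV_max = Inf)
  ## independent recomputation: q = 2^-Ct, M_j = mean_k sd(log2(q_j/q_k))
  q <- 2^(-wide)
  oracle <- sapply(colnames(wide), function(j) {
    mean(sapply(setdiff(colnames(wide), j), function(k)
      sd(log2(q[, j] / q[, k]))))
  })
  expect_equal(st$M, oracle, tolerance = 1e-12)
  ## monotone in injected noise on one gene
  Ms <- vapply(c(0.1, 0.3, 0.6), function(s) {
    set.seed(5)
    ctn <- ct
    ctn$ct[ctn$target == "g1"] <- wide[, "g1"] + rnorm(6, 0, s)
    genormStability(ctn, colnames(wide), M_max = Inf, CV_max = Inf)$M[["g1"]]
  }, numeric(1))
  expect_true(all(diff(Ms) > 0))
})

test_that("ddctExpression recovers planted fold-changes and normalizes the reference", {
  samples <- sprintf("m%02d", 1:12)
  grp <- setNames(rep(c("CTRL", "MS"), each = 6), samples)
  shift <- rnorm(12, 0, 0.5)  # per-sample RT efficiency, must cancel
  ## target 1 cycle lower in every sample vs reference mean -> rel_expr 2
  tct <- 24 - ifelse(grp == "MS", 1, 0) + shift
  ct <- rbind(ctRows(samples, "tgt", "cDNA", tct),
              ctRows(samples, "hk1", "cDNA", 20 + shift),
              ctRows(samples, "hk2", "cDNA", 22 + shift))
  ex <- ddctExpression(ct, "tgt", c("hk1", "hk2"), grp)
  fc <- ex$group_fc
  expect_equal(fc$fold_change[fc$group == "MS"], 2, tolerance = 1e-9)
  ## reference-group geometric mean is exactly 1
  refRel <- ex$samples$rel_expr[ex$samples$group == "CTRL"]
  expect_equal(exp(mean(log(refRel))), 1, tolerance = 1e-9)
  ## sample whose dCt equals the reference mean has rel_expr 1
  ctrlRows <- ex$samples[ex$samples$group == "CTRL", ]
  expect_equal(ctrlRows$rel_expr[which.min(abs(ctrlRows$ddct))],
               2^(-min(abs(ctrlRows$ddct))), tolerance = 1e-12)
  expect_error(ddctExpression(ct, "tgt", c("hk1", "hk2"), grp,
                              reference_group = "HD"), "reference group")
})

test_that("groupStats reduces to the pooled t-test with two groups", {
  set.seed(9)
  v <- c(rnorm(8, 10), rnorm(8, 11))
  g <- rep(c("A", "B"), each = 8)
  gs <- groupStats(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(gs$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(gs$lsd$p, tt$p.value, tolerance = 1e-9)
  expect_error(groupStats(v, rep("A", 16)), "2 groups")
  expect_error(groupStats(v[1:3], c("A", "A", "B")), "2 samples")
})

test_that("groupStats holds its type-I error and loses significance under permutation", {
  set.seed(14)
  g <- rep(c("A", "B", "C"), each = 6)
  rejections <- mean(replicate(2000, groupStats(rnorm(18), g)$p <= 0.05))
  expect_gt(rejections, 0.05 - 2.5 * sqrt(0.05 * 0.95 / 2000))
  expect_lt(rejections, 0.05 + 2.5 * sqrt(0.05 * 0.95 / 2000))
  ## a strongly significant dataset loses significance under label permutation
  v <- c(rnorm(6, 0), rnorm(6, 3), rnorm(6, 6))
  p0 <- groupStats(v, g)$p
  permP <- replicate(200, groupStats(v, sample(g))$p)
  expect_lt(p0, 0.001)
  expect_gt(median(permP), 0.05)
})

test_that("Ct tables round-trip through TSV and reject invalid values", {
  ct <- rbind(ctRows("s1", "pos", "input", 25), ctRows("s1", "pos", "IP", 19))
  f <- tempfile(fileext = ".tsv")
  write.table(ct, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(readCtTable(f), ct)
  bad <- ct; bad$ct[1] <- -2
  f2 <- tempfile(fileext = ".tsv")
  write.table(bad, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readCtTable(f2), "positive")
})
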