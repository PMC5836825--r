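test_that("foldChangeOverMean computes log2 ratios to the row mean", {
  m <- rbind(r1 = c(2, 2, 2, 2), r2 = c(1, 1, 1, 5))
  colnames(m) <- paste0("s", 1:4)
  vp <- foldChangeOverMean(m)
  expect_equal(unname(vp@fcOverMean["r1", ]), rep(0, 4))
  expect_equal(unname(vp@fcOverMean["r2", 4]), log2(5 / 2), tolerance = 1e-12)
  ## invariant: each row of 2^fc has mean 1
  k <- nbMatrix(100, 6, mu = 50, alpha = 0.1, seed = 2) + 1
  vp2 <- foldChangeOverMean(k)
  expect_equal(unname(rowMeans(2^vp2@fcOverMean)), rep(1, 100), tolerance = 1e-9)
  expect_true(all(vp2@fractionWithinTwofold >= 0 & vp2@fractionWithinTwofold <= 1))
  expect_error(foldChangeOverMean(m[, 1, drop = FALSE]), "two samples")
})

test_that("fraction within two-fold shrinks as dispersion grows", {
  frac <- vapply(c(0.01, 0.6), function(a) {
    sm <- smallSim(23, dispersion = a, loading = 0, n_de_regions = 0)
    median(foldChangeOverMean(2^enrichValues(normalizeLog2(sm$sim$broad)))@fractionWithinTwofold)
  }, numeric(1))
  expect_gt(frac[1], 0.9)
  expect_gt(frac[1], frac[2])
})

test_that("topVariable ranks by variance with deterministic tie-break", {
  m <- rbind(flat = c(3, 3, 3, 3), wig = c(1, 5, 1, 5), mid = c(2, 3, 2, 3))
  colnames(m) <- paste0("s", 1:4)
  expect_equal(topVariable(m, 3), c("wig", "mid", "flat"))
  expect_equal(topVariable(m, 1), "wig")
  expect_error(topVariable(m, 0))
  expect_error(topVariable(m, 4))
})

test_that("correlationWithP matches a permutation oracle within Monte-Carlo error", {
  set.seed(99)
  n <- 10
  m <- rbind(x = rnorm(n), y = rnorm(n), z = rnorm(n))
  m["y", ] <- 0.7 * m["x", ] + 0.7 * m["y", ]
  colnames(m) <- paste0("s", 1:n)
  cw <- correlationWithP(m)
  expect_equal(diag(cw$r), rep(1, 3), ignore_attr = TRUE)
  ## y = -x gives r = -1
  neg <- rbind(a = 1:6, b = -(1:6)); colnames(neg) <- paste0("s", 1:6)
  expect_equal(correlationWithP(neg)$r["a", "b"], -1)
  ## permutation oracle (1e4 permutations) for each off-diagonal pair
  permP <- function(a, b, B = 1e4) {
    r0 <- abs(cor(a, b))
    set.seed(1)
    mean(replicate(B, abs(cor(a, sample(b)))) >= r0 - 1e-12)
  }
  for (pr in list(c("x", "y"), c("x", "z"), c("y", "z"))) {
    pp <- permP(m[pr[1], ], m[pr[2], ])
    expect_lt(abs(cw$p[pr[1], pr[2]] - pp), 0.03)
  }
  ## zero-variance rows flagged undefined
  m2 <- rbind(m, const = rep(1, n))
  cw2 <- correlationWithP(m2)
  expect_equal(cw2$undefined, "const")
  expect_true(all(is.na(cw2$r["const", setdiff(rownames(m2), "const")])))
  expect_error(correlationWithP(m[, 1:3]), "4 samples")
})

test_that("extractOpposingSubset solves constructed cases", {
  ## two perfect anti-correlated pairs across clusters -> 2 + 2 split
  f <- c(1, -1, 2, -2, 0.5, -0.5, 1.5, -1.2)
  m <- rbind(a1 = f, a2 = f + rnorm(8, 0, 1e-3),
             b1 = -f, b2 = -f + rnorm(8, 0, 1e-3))
  colnames(m) <- paste0("s", 1:8)
  cw <- correlationWithP(m)
  res <- extractOpposingSubset(cw)
  expect_setequal(selectedIds(res), c("a1", "a2", "b1", "b2"))
  lab <- clusterLabels(res)
  expect_equal(lab[["a1"]], lab[["a2"]])
  expect_equal(lab[["b1"]], lab[["b2"]])
  expect_false(lab[["a1"]] == lab[["b1"]])
  ## partners point across clusters
  pm <- partnerMap(res)
  expect_true(all(pm$partner_r < -0.9))

  ## all-positive correlations -> empty subset with a warning
  pos <- rbind(p1 = f, p2 = f + rnorm(8, 0, 1e-3), p3 = f + rnorm(8, 0, 1e-3))
  colnames(pos) <- paste0("s", 1:8)
  expect_warning(res0 <- extractOpposingSubset(correlationWithP(pos)),
                 "no significant negative")
  expect_length(selectedIds(res0), 0)
})

test_that("extraction is deterministic and label-symmetric on simulated data", {
  sm <- smallSim(41)
  norm <- normalizeLog2(sm$sim$broad)
  cw <- correlationWithP(norm, subset = topVariable(norm, 100))
  r1 <- extractOpposingSubset(cw)
  r2 <- extractOpposingSubset(cw)
  expect_identical(selectedIds(r1), selectedIds(r2))
  expect_identical(clusterLabels(r1), clusterLabels(r2))
  ## subset invariant holds for every member after pruning
  lab <- clusterLabels(r1)
  sig <- cw$p <= 0.01 & !is.na(cw$r)
  for (id in selectedIds(r1)) {
    same <- setdiff(selectedIds(r1)[lab == lab[[id]]], id)
    other <- selectedIds(r1)[lab != lab[[id]]]
    expect_true(any(cw$r[id, same] >= 0.8 & sig[id, same]))
    expect_true(any(cw$r[id, other] <= -0.8 & sig[id, other]))
  }
})

test_that("null data rarely yields a non-empty opposing subset", {
  nonEmpty <- vapply(1:100, function(s) {
    k <- nbMatrix(200, 12, mu = 100, alpha = 0.05, seed = 1000 + s)
    lm2 <- log2(k + 1)
    cw <- correlationWithP(lm2, subset = topVariable(lm2, 100))
    res <- suppressWarnings(extractOpposingSubset(cw))
    length(selectedIds(res))
  }, numeric(1))
  expect_equal(median(nonEmpty), 0)
})

test_that("pcaVariance behaves at the rank-1 limit and under pure noise", {
  ## rank-1: single factor, no noise -> PC1 fraction 1
  f <- rnorm(12); load <- rnorm(50)
  m1 <- outer(load, f)
  dimnames(m1) <- list(sprintf("r%02d", 1:50), sprintf("s%02d", 1:12))
  pv <- pcaVariance(m1)
  expect_equal(pv$var_frac[1], 1, tolerance = 1e-9)
  ## isotropic noise: PC1 fraction near the small-sample expectation from
  ## an independent simulation of the same null
  set.seed(4)
  obs <- pcaVariance(matrix(rnorm(500 * 12), 500, 12))$var_frac[1]
  null1 <- replicate(40, pcaVariance(matrix(rnorm(500 * 12), 500, 12))$var_frac[1])
  expect_lt(abs(obs - mean(null1)), 4 * sd(null1) + 0.01)
  ## metadata association p-values returned when meta given
  sm <- smallSim(13)
  pvm <- pcaVariance(normalizeLog2(sm$sim$broad), meta = sm$sim$meta)
  expect_named(pvm$association, c("group", "litter", "library_total"))
  expect_true(all(pvm$association >= 0 & pvm$association <= 1))
})

test_that("planted opposing clusters are recovered and concentrate PC1 variance", {
  sm <- smallSim(57)
  norm <- normalizeLog2(sm$sim$broad)
  cov <- covariationAnalysis(norm, meta = sm$sim$meta, k = 150)
  truthIds <- unlist(sm$sim$truth$cluster_members)
  sel <- selectedIds(cov)
  expect_gte(sum(truthIds %in% sel) / length(truthIds), 0.9)
  expect_lte(sum(!(sel %in% truthIds)) / max(length(sel), 1), 0.1)
  ## the two clusters match the planted partition (up to label swap)
  lab <- clusterLabels(cov)
  tA <- intersect(sm$sim$truth$cluster_members$A, sel)
  tB <- intersect(sm$sim$truth$cluster_members$B, sel)
  expect_equal(length(unique(lab[tA])), 1)
  expect_equal(length(unique(lab[tB])), 1)
  expect_false(lab[[tA[1]]] == lab[[tB[1]]])
  ## PC1 fraction larger on the subset than on the full set
  pv <- pcVariance(cov)
  expect_gt(pv$subset[1], pv$full[1])
})
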