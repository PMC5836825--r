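test_that("bhAdjust equals the brute-force step-up definition and p.adjust", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  bruteBH <- function(p) {
    m <- length(p); o <- order(p)
    q <- numeric(m)
    for (k in seq_len(m)) q[o[k]] <- min(1, min(m * p[o[k:m]] / rank(p)[o[k:m]]))
    q
  }
  set.seed(10)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    expect_equal(bhAdjust(p), bruteBH(p), tolerance = 1e-12)
    expect_equal(bhAdjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
  ## NA p-values excluded from m and propagated
  p <- c(0.01, NA, 0.04)
  q <- bhAdjust(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], p.adjust(p, "BH")[c(1, 3)])
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("dispersion estimation recovers truth under Poisson and NB data", {
  grp <- rep(c("CTRL", "MS"), each = 4)
  ## Poisson (alpha = 0): estimates collapse toward the floor
  set.seed(21)
  kp <- matrix(rpois(2000 * 8, lambda = 150), 2000, 8,
               dimnames = list(sprintf("r%04d", 1:2000), paste0("s", 1:8)))
  dp <- estimateDispersions(kp, grp, rep(1, 8))
  expect_lte(median(dp), 0.01)
  ## NB with alpha = 0.05
  kn <- nbMatrix(2000, 8, mu = 150, alpha = 0.05, seed = 22)
  dn <- estimateDispersions(kn, grp, rep(1, 8))
  expect_gte(median(dn), 0.03)
  expect_lte(median(dn), 0.08)
  ## constant counts -> floor
  kc <- matrix(7, 10, 8, dimnames = list(sprintf("c%02d", 1:10), paste0("s", 1:8)))
  expect_equal(as.numeric(estimateDispersions(kc, grp, rep(1, 8), w = 0)),
               rep(1e-8, 10))
  expect_error(estimateDispersions(kn, c(rep("A", 7), "B"), rep(1, 8)),
               "at least 2")
})

test_that("the NB Wald fit matches the group-mean ratio in the balanced equal-sf case", {
  k <- nbMatrix(300, 8, mu = 200, alpha = 0.05, seed = 33)
  grp <- rep(c("CTRL", "MS"), each = 4)
  disp <- setNames(rep(0.05, 300), rownames(k))
  tt <- suppressWarnings(nbWaldTest(k, grp, c("MS", "CTRL"),
                                    sizeFactors = rep(1, 8), dispersions = disp))
  m0 <- rowMeans(k[, 1:4]); m1 <- rowMeans(k[, 5:8])
  ok <- tt$converged & m0 > 0 & m1 > 0
  expect_gt(mean(ok), 0.99)
  expect_equal(tt$log2fc[ok], log2(m1 / m0)[ok], tolerance = 1e-6)
})

test_that("planted log2 fold-changes are recovered and degenerate regions flagged", {
  set.seed(44)
  n <- 500
  mu <- cbind(matrix(500, n, 4), matrix(1000, n, 4))  # true log2fc = 1
  k <- matrix(rnbinom(n * 8, mu = mu, size = 1 / 0.01), n, 8,
              dimnames = list(sprintf("r%04d", 1:n), paste0("s", 1:8)))
  k <- rbind(k, zero = rep(0L, 8))
  grp <- rep(c("CTRL", "MS"), each = 4)
  tt <- suppressWarnings(nbWaldTest(k, grp, c("MS", "CTRL"),
                                    sizeFactors = rep(1, 8)))
  expect_gte(median(tt$log2fc[1:n], na.rm = TRUE), 0.8)
  expect_lte(median(tt$log2fc[1:n], na.rm = TRUE), 1.2)
  expect_false(tt$converged[tt$region_id == "zero"])
  expect_true(is.na(tt$pvalue[tt$region_id == "zero"]))
})

test_that("nbWaldTest is calibrated on null NB data", {
  ## 2000 null regions here (the full 5000-region battery runs in the
  ## acceptance suite); size must sit near the nominal level
  k <- nbMatrix(2000, 8, mu = 120, alpha = 0.05, seed = 55)
  grp <- rep(c("CTRL", "MS"), each = 4)
  sf <- sizeFactorsMedianRatio(k)
  tt <- suppressWarnings(nbWaldTest(k, grp, c("MS", "CTRL"), sizeFactors = sf))
  size <- mean(tt$pvalue <= 0.05, na.rm = TRUE)
  expect_gt(size, 0.035)
  expect_lt(size, 0.065)
})

test_that("dePeakWorkflow applies FDR, promoter and input-bias filters", {
  sm <- smallSim(61)
  ps <- assignPeaks(sm$sim$peaks, sm$ann$tss)
  de <- dePeakWorkflow(sm$sim$broad, sm$sim$meta$group, ps,
                       inputCounts = sm$sim$input,
                       contrasts = list(c("MS", "CTRL")))
  ## call hierarchy: final subset of FDR-passing subset of tested
  expect_true(all(de$passes_fdr[de$final]))
  expect_true(all(de$in_promoter[de$final]))
  expect_true(all(de$input_bias_ok[de$final]))
  ## planted 4-fold input-bias regions are excluded even when q <= fdr
  bias <- de[de$region_id %in% sm$sim$truth$biased_input_regions, ]
  expect_true(any(bias$passes_fdr))          # they do look enriched
  expect_true(all(!bias$final))              # but the bias filter removes them
  expect_true(all(!bias$input_bias_ok))
  ## missing input: filter skipped with warning, flag NA
  expect_warning(de2 <- dePeakWorkflow(sm$sim$broad, sm$sim$meta$group, ps,
                                       contrasts = list(c("MS", "CTRL"))),
                 "input")
  expect_true(all(is.na(de2$input_bias_ok)))
})

test_that("windowWorkflow rejects uniform coverage and finds a planted domain", {
  seqlen <- c(chrS = 100000L)
  grp <- rep(c("CTRL", "MS"), each = 2)
  ## uniform coverage: nothing is 5-fold over global background
  set.seed(71)
  unif <- lapply(1:4, function(i)
    fragsAtMidpoints(sort(sample(200:99800, 4000, replace = TRUE)), chrom = "chrS"))
  names(unif) <- paste0("u", 1:4)
  expect_error(windowWorkflow(unif, grp, seqlen,
                              contrasts = list(c("MS", "CTRL"))),
               "abundance filter")
  ## planted 600-bp enriched domain -> one merged region of >= 3 windows
  planted <- lapply(1:4, function(i) {
    bg <- sample(200:99800, 2000, replace = TRUE)
    hot <- sample(50000:50599, 1500, replace = TRUE)
    fragsAtMidpoints(c(bg, hot), chrom = "chrS")
  })
  names(planted) <- paste0("p", 1:4)
  ww <- suppressWarnings(windowWorkflow(planted, grp, seqlen,
                                        contrasts = list(c("MS", "CTRL"))))
  hit <- ww[ww$start <= 50600 & ww$end >= 50000, ]
  expect_gte(nrow(hit), 1)
  expect_gte(max(hit$n_windows), 3)
})
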