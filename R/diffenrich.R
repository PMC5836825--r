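## Negative-binomial differential enrichment (peak resolution).
##
## The NB machinery is written from scratch: method-of-moments dispersions
## shrunk toward a fitted mean-dispersion trend, a per-region NB GLM with log
## link fit by IRLS, Wald tests, and Benjamini-Hochberg adjustment. The
## variance model is var = mu + alpha * mu^2.

#' Per-region NB dispersion estimates with trend shrinkage
#'
#' Method-of-moments estimate on normalized counts, pooling residual variance
#' within groups: \eqn{\hat\alpha_i = \max(floor, (s^2_i - \hat\mu_i)/\hat\mu_i^2)}.
#' A mean-dispersion trend \eqn{\alpha_{tr}(\mu) = a_0 + a_1/\mu} is fitted by
#' a binned moment regression (regions binned by mean, per-bin dispersion from
#' pooled moments — this avoids the small-sample bias of averaging per-region
#' ratios) and each raw estimate is shrunk toward it:
#' \eqn{\alpha = (1-w)\hat\alpha + w\,\alpha_{tr}}.
#'
#' @param object an \code{EnrichmentMatrix} of raw counts, or a count matrix
#'   (methods are registered on the \code{BiocGenerics} generic)
#' @param group factor/character of group labels, one per sample; every group
#'   needs at least 2 samples
#' @param sizeFactors per-sample size factors (computed when NULL)
#' @param w shrinkage weight toward the trend, in [0,1] (default 0.9: with
#'   few replicates the per-region moment estimate is very noisy, so the
#'   trend dominates; see the package vignette for the calibration rationale)
#' @param floor minimum dispersion (default 1e-8)
#' @return named numeric vector of per-region dispersions, with the raw
#'   estimates and trend coefficients in attributes \code{"raw"} and
#'   \code{"trend"}
#' @aliases estimateDispersions
#' @name estimateDispersions
NULL

.estimateDispersions <- function(k, group, sizeFactors = NULL, w = 0.9,
                                 floor = 1e-8) {
  group <- as.factor(group)
  if (length(group) != ncol(k)) stop("one group label per sample required")
  if (any(table(group) < 2)) stop("every group needs at least 2 samples")
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianRatio(k)
  q <- sweep(k, 2, sizeFactors, "/")
  n <- ncol(q); G <- nlevels(group)
  groupMeans <- t(rowsum(t(q), group) / as.vector(table(group)))
  resid <- q - groupMeans[, as.integer(group)]
  s2 <- rowSums(resid^2) / (n - G)
  mu <- rowMeans(q)
  alphaRaw <- ifelse(mu > 0, (s2 - mu) / mu^2, NA_real_)
  ## trend fit alpha ~ a0 + a1/mu by binned pooled moments: per mean-bin,
  ## alpha_b = (mean s2 - mean mu) / mean(mu^2); then weighted least squares
  use <- which(!is.na(alphaRaw) & mu > 0)
  a0 <- 0; a1 <- 0
  if (length(use) >= 50) {
    nb <- min(20L, max(2L, floor(length(use) / 25)))
    br <- unique(stats::quantile(mu[use], seq(0, 1, length.out = nb + 1)))
    bins <- cut(mu[use], br, include.lowest = TRUE)
    ab <- tapply(use, bins, function(ix) (mean(s2[ix]) - mean(mu[ix])) / mean(mu[ix]^2))
    mb <- tapply(mu[use], bins, mean)
    nbin <- tapply(use, bins, length)
    ok <- !is.na(ab) & !is.na(mb)
    if (sum(ok) >= 3) {
      fit <- stats::lm(ab[ok] ~ I(1 / mb[ok]), weights = nbin[ok])
      cf <- stats::coef(fit)
      a0 <- max(0, unname(cf[1])); a1 <- max(0, unname(cf[2]))
    } else {
      a0 <- max(0, stats::weighted.mean(ab[ok], nbin[ok]))
    }
  } else if (length(use)) {
    a0 <- max(0, stats::median(alphaRaw[use]))
  }
  trend <- a0 + a1 / pmax(mu, .Machine$double.eps)
  alpha <- (1 - w) * pmax(alphaRaw, floor) + w * trend
  ## dispersion outliers far above the trend keep their raw estimate:
  ## shrinking them would underprice their variance and inflate the far
  ## tail of the Wald statistic
  outlier <- !is.na(alphaRaw) & alphaRaw > 3 * pmax(trend, floor)
  alpha[outlier] <- alphaRaw[outlier]
  alpha <- pmax(alpha, floor)
  alpha[is.na(alphaRaw)] <- NA_real_
  out <- stats::setNames(alpha, rownames(k))
  attr(out, "raw") <- stats::setNames(pmax(alphaRaw, floor), rownames(k))
  attr(out, "trend") <- c(a0 = a0, a1 = a1)
  out
}

#' @rdname estimateDispersions
#' @export
setMethod("estimateDispersions", "matrix",
  function(object, group, sizeFactors = NULL, w = 0.9, floor = 1e-8)
    .estimateDispersions(object, group, sizeFactors, w, floor))

#' @rdname estimateDispersions
#' @export
setMethod("estimateDispersions", "EnrichmentMatrix",
  function(object, group, sizeFactors = NULL, w = 0.9, floor = 1e-8)
    .estimateDispersions(enrichValues(object), group, sizeFactors, w, floor))

## Vectorized IRLS for per-region NB GLMs with log link, offset log(sf), and
## a two-level group design (intercept + indicator). All regions iterate
## simultaneously via closed-form 2x2 solves.
.nbGlmTwoGroup <- function(k, sf, x, alpha, tol = 1e-8, maxit = 100) {
  p <- nrow(k); n <- ncol(k)
  q <- sweep(k, 2, sf, "/")
  m0 <- rowMeans(q[, x == 0, drop = FALSE]); m1 <- rowMeans(q[, x == 1, drop = FALSE])
  eps <- 0.1
  b0 <- log(m0 + eps); b1 <- log(m1 + eps) - log(m0 + eps)
  usable <- rowSums(k) > 0 & m0 > 0 & m1 > 0 & !is.na(alpha)
  conv <- rep(FALSE, p)
  xi <- which(x == 1)
  for (it in seq_len(maxit)) {
    eta <- b0 + outer(b1, as.numeric(x))
    mu <- sweep(exp(eta), 2, sf, "*")
    wgt <- mu / (1 + alpha * mu)
    z <- eta + (k - mu) / mu
    wz <- wgt * z
    S0 <- rowSums(wgt); S1 <- rowSums(wgt[, xi, drop = FALSE])
    T0 <- rowSums(wz); T1 <- rowSums(wz[, xi, drop = FALSE])
    det <- S1 * (S0 - S1)
    ok <- usable & det > 1e-12 & is.finite(det)
    nb0 <- ifelse(ok, (S1 * T0 - S1 * T1) / det, b0)
    nb1 <- ifelse(ok, (S0 * T1 - S1 * T0) / det, b1)
    delta <- pmax(abs(nb0 - b0), abs(nb1 - b1))
    b0 <- nb0; b1 <- nb1
    newconv <- ok & delta < tol
    conv <- conv | newconv
    if (all(conv | !usable)) break
  }
  eta <- b0 + outer(b1, as.numeric(x))
  mu <- sweep(exp(eta), 2, sf, "*")
  wgt <- mu / (1 + alpha * mu)
  S0 <- rowSums(wgt); S1 <- rowSums(wgt[, xi, drop = FALSE])
  det <- S1 * (S0 - S1)
  se <- ifelse(conv & det > 0, sqrt(S0 / det), NA_real_)
  list(beta0 = b0, beta1 = b1, se = se, converged = conv & usable,
       baseMean = rowMeans(q))
}

#' NB Wald test for differential enrichment between two groups
#'
#' Per-region negative-binomial GLM with log link and design ~ group, fitted
#' by iteratively reweighted least squares (tolerance 1e-8, at most 100
#' iterations) with the size factors as offsets and fixed per-region
#' dispersions. The Wald statistic \eqn{z = \hat\beta / SE(\hat\beta)} is
#' referred to the standard normal (two-sided). Non-converged or degenerate
#' regions (e.g. all-zero, or one group entirely zero) are flagged and get NA
#' p-values.
#'
#' @param counts an \code{EnrichmentMatrix} of raw counts (or matrix)
#' @param group group labels, one per sample
#' @param contrast length-2 character: (test group, reference group)
#' @param sizeFactors per-sample size factors (computed when NULL)
#' @param dispersions per-region dispersions (estimated when NULL)
#' @return a \code{DataFrame}: region_id, baseMean, log2fc, se (of log2fc),
#'   stat, pvalue, dispersion, converged
#' @export
nbWaldTest <- function(counts, group, contrast, sizeFactors = NULL,
                       dispersions = NULL) {
  k <- if (methods::is(counts, "EnrichmentMatrix")) enrichValues(counts) else as.matrix(counts)
  group <- as.character(group)
  if (length(contrast) != 2 || !all(contrast %in% group))
    stop("contrast groups must both be present in 'group'")
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianRatio(k)
  if (is.null(dispersions))
    dispersions <- estimateDispersions(k, group, sizeFactors)
  use <- group %in% contrast
  ku <- k[, use, drop = FALSE]
  sfu <- sizeFactors[use]
  x <- as.numeric(group[use] == contrast[1])
  fit <- .nbGlmTwoGroup(ku, sfu, x, dispersions)
  log2fc <- fit$beta1 / log(2)
  se2 <- fit$se / log(2)
  stat <- fit$beta1 / fit$se
  pv <- 2 * stats::pnorm(-abs(stat))
  bad <- !fit$converged
  log2fc[bad] <- ifelse(rowSums(ku[bad, , drop = FALSE]) == 0, NA, log2fc[bad])
  pv[bad] <- NA_real_
  if (any(bad))
    warning(sprintf("%d regions flagged (non-converged or degenerate); excluded from testing",
                    sum(bad)))
  S4Vectors::DataFrame(region_id = rownames(k), baseMean = fit$baseMean,
                       log2fc = log2fc, se = se2, stat = stat, pvalue = pv,
                       dispersion = unname(dispersions),
                       converged = fit$converged)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment \eqn{q_{(k)} = \min_{j \ge k} m\,p_{(j)}/j} returned in
#' the original order. NA p-values are excluded from m and propagate as NA.
#'
#' @param p numeric vector of p-values in [0,1] (NA allowed)
#' @return numeric vector of q-values
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bhAdjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  idx <- which(!is.na(p))
  m <- length(idx)
  if (!m) return(q)
  o <- order(p[idx])
  ps <- p[idx][o]
  qs <- pmin(1, rev(cummin(rev(m * ps / seq_len(m)))))
  q[idx[o]] <- qs
  q
}

#' Peak-level differential enrichment workflow with post-filters
#'
#' Full pipeline: optional blacklist filtering, median-of-ratios size
#' factors, dispersion estimation on all groups, an NB Wald test per contrast
#' (each stress group vs the reference), BH adjustment within each contrast,
#' then the two post-filters: the region must lie in a promoter (have at
#' least one assigned gene on the annotated \code{PeakSet}) and show no
#' substantial input bias (absolute log2 ratio of group-mean input coverage
#' at most \code{bias_log2_max}; regions with less than
#' \code{min_input_depth} total input fragments are treated as unassessable
#' and pass). A final call is the conjunction of all flags.
#'
#' @param counts an \code{EnrichmentMatrix} of raw peak counts
#' @param group group labels, one per sample
#' @param peaks the annotated \code{PeakSet} the counts were made on
#' @param inputCounts optional \code{EnrichmentMatrix} of input (background)
#'   coverage over the same regions, with a \code{group} column in its
#'   colData; when NULL the bias filter is skipped with a warning and the
#'   flag is NA
#' @param contrasts list of length-2 character vectors (test, reference);
#'   default \code{list(c("HD","CTRL"), c("MS","CTRL"))}
#' @param fdr FDR threshold (default 0.10)
#' @param bias_log2_max maximum absolute log2 input-coverage group ratio
#'   (default 1.0)
#' @param min_input_depth minimum total input fragments to assess bias
#'   (default 10)
#' @param blacklist optional GRanges of regions to exclude up front
#' @return a \code{DataFrame} of per-region, per-contrast calls with columns
#'   region_id, contrast, baseMean, log2fc, pvalue, qvalue, passes_fdr,
#'   in_promoter, input_bias_ok, final, genes, bidirectional; the fraction of
#'   final calls in bidirectional promoters is attached as attribute
#'   \code{"bidirectional_fraction"} in \code{metadata}
#' @export
dePeakWorkflow <- function(counts, group, peaks, inputCounts = NULL,
                           contrasts = list(c("HD", "CTRL"), c("MS", "CTRL")),
                           fdr = 0.10, bias_log2_max = 1.0,
                           min_input_depth = 10, blacklist = NULL) {
  stopifnot(methods::is(counts, "EnrichmentMatrix"))
  if (!is.null(blacklist)) {
    peaks <- subtractBlacklist(peaks, blacklist)
    keep <- intersect(regionIds(counts), peakIds(peaks))
    counts <- counts[keep, ]
  }
  k <- enrichValues(counts)
  ids <- rownames(k)
  sf <- sizeFactorsMedianRatio(k)
  disp <- estimateDispersions(k, group, sf)
  ga <- geneAssignments(peaks)
  bd <- isBidirectional(peaks)
  inProm <- stats::setNames(ids %in% names(ga)[vapply(ga, length, integer(1)) > 0], ids)
  genes <- vapply(ids, function(i)
    paste(if (i %in% names(ga)) ga[[i]] else character(0), collapse = ","), character(1))
  ## input bias per contrast
  biasFlag <- function(contrast) {
    if (is.null(inputCounts)) {
      warning("no input counts provided; input-bias filter skipped (flag NA)")
      return(stats::setNames(rep(NA, length(ids)), ids))
    }
    ik <- enrichValues(inputCounts)[ids, , drop = FALSE]
    ig <- as.character(SummarizedExperiment::colData(inputCounts)$group)
    if (is.null(ig)) stop("inputCounts colData must carry a 'group' column")
    mTest <- rowMeans(ik[, ig == contrast[1], drop = FALSE])
    mRef <- rowMeans(ik[, ig == contrast[2], drop = FALSE])
    shallow <- rowSums(ik[, ig %in% contrast, drop = FALSE]) < min_input_depth
    ratio <- log2((mTest + 0.5) / (mRef + 0.5))
    stats::setNames(abs(ratio) <= bias_log2_max | shallow, ids)
  }
  res <- lapply(contrasts, function(ct) {
    tt <- nbWaldTest(counts, group, ct, sizeFactors = sf, dispersions = disp)
    q <- bhAdjust(tt$pvalue)
    passes <- !is.na(q) & q <= fdr
    bias <- biasFlag(ct)
    final <- passes & inProm[ids] & (is.na(bias) | bias)
    S4Vectors::DataFrame(region_id = ids, contrast = paste(ct, collapse = "_vs_"),
                         baseMean = tt$baseMean, log2fc = tt$log2fc,
                         pvalue = tt$pvalue, qvalue = q,
                         passes_fdr = passes, in_promoter = unname(inProm[ids]),
                         input_bias_ok = unname(bias), final = final,
                         genes = genes, bidirectional = unname(bd[ids]))
  })
  out <- do.call(rbind, res)
  fin <- out[out$final & !is.na(out$final), , drop = FALSE]
  bf <- if (nrow(fin)) mean(fin$bidirectional, na.rm = TRUE) else NA_real_
  S4Vectors::metadata(out)$bidirectional_fraction <- bf
  S4Vectors::metadata(out)$thresholds <- list(fdr = fdr,
                                              bias_log2_max = bias_log2_max,
                                              min_input_depth = min_input_depth)
  out
}
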