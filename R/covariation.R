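## Inter-individual variability and opposing-cluster covariation analysis.
##
## The central question: across individuals, do the most variable promoter
## peaks fluctuate independently, or does a single latent sample factor drive
## them, loading one set of peaks positively and another negatively?  The
## extraction below formalizes that as seeded bipartite growth over the
## thresholded correlation graph.

#' Fold-changes over the cross-sample mean enrichment
#'
#' For each region, the per-sample log2 fold-change over the region's mean
#' (linear-scale) enrichment across all samples. Rows with zero mean are
#' dropped with a warning.
#'
#' @param x an \code{EnrichmentMatrix} (log2-normalized values are converted
#'   back to the linear scale first) or a linear-scale matrix
#' @return a \code{\link{VariabilityProfile}}
#' @export
foldChangeOverMean <- function(x) {
  lin <- if (methods::is(x, "EnrichmentMatrix")) {
    if (isNormalized(x)) 2^enrichValues(x) else enrichValues(x)
  } else as.matrix(x)
  if (ncol(lin) < 2) stop("need at least two samples")
  rm <- rowMeans(lin)
  if (any(rm == 0)) {
    warning(sprintf("dropping %d regions with zero mean enrichment", sum(rm == 0)))
    lin <- lin[rm > 0, , drop = FALSE]
    rm <- rm[rm > 0]
  }
  fc <- log2(lin / rm)
  frac <- apply(fc, 2, function(col) mean(abs(col) <= 1))
  spread <- data.frame(sample_id = colnames(lin),
                       sd = apply(fc, 2, stats::sd),
                       iqr = apply(fc, 2, stats::IQR),
                       row.names = NULL)
  methods::new("VariabilityProfile", fcOverMean = fc, perSampleSpread = spread,
               fractionWithinTwofold = frac)
}

#' Most variable regions
#'
#' Regions ranked by cross-sample variance of log2 enrichment; ties broken by
#' region id so the selection is deterministic.
#'
#' @param x a normalized \code{EnrichmentMatrix} or a log2 matrix
#' @param k number of regions to return (default 1000)
#' @return character vector of the top-\code{k} region ids
#' @export
topVariable <- function(x, k = 1000) {
  m <- if (methods::is(x, "EnrichmentMatrix")) enrichValues(x) else as.matrix(x)
  if (k <= 0) stop("k must be positive")
  if (k > nrow(m)) stop("k exceeds the number of regions")
  v <- apply(m, 1, stats::var)
  ids <- rownames(m)
  ids[order(-v, ids)][seq_len(k)]
}

#' Pairwise region correlations with p-values
#'
#' Pearson (or Spearman) correlation between regions across samples, with
#' two-sided p-values from the t statistic
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on n - 2 degrees of freedom. Regions with
#' zero variance get NA correlations (flagged, excluded downstream).
#'
#' @param x a normalized \code{EnrichmentMatrix} or a log2 matrix (regions x
#'   samples)
#' @param subset optional region ids to restrict to
#' @param method \code{"pearson"} (default) or \code{"spearman"}
#' @return list with matrices \code{r} and \code{p}, the sample count
#'   \code{n}, and \code{undefined} (ids of zero-variance regions)
#' @export
correlationWithP <- function(x, subset = NULL, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- if (methods::is(x, "EnrichmentMatrix")) enrichValues(x) else as.matrix(x)
  if (!is.null(subset)) m <- m[subset, , drop = FALSE]
  n <- ncol(m)
  if (n < 4) stop("need at least 4 samples for correlation p-values")
  zv <- apply(m, 1, stats::var) == 0
  r <- suppressWarnings(stats::cor(t(m), method = method))
  r[zv, ] <- NA; r[, zv] <- NA
  rc <- pmin(pmax(r, -1), 1)
  tstat <- rc * sqrt((n - 2) / pmax(1 - rc^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rc) >= 1 - 1e-12] <- 0
  diag(r) <- 1; diag(p) <- 0
  list(r = r, p = p, n = n, undefined = rownames(m)[zv])
}

#' Extract the opposing two-cluster covariation subset
#'
#' Formalizes the selection of co-varying peaks as seeded bipartite growth on
#' the thresholded correlation graph: (1) seed the two clusters with the most
#' negative significant pair; (2) iteratively admit any region with a
#' significant correlation >= \code{r_pos} to a member of one cluster and
#' <= \code{-r_neg} to a member of the other, assigning it to the positively
#' matching side (if both sides match positively, the side with the stronger
#' positive correlation wins); (3) iterate to a fixpoint; (4) prune members
#' that lack a qualifying positive partner within their own cluster or a
#' qualifying negative partner in the other, to a fixpoint. Each selected
#' region is also given its single most negatively correlated partner over
#' the whole analyzed set (duplicates allowed).
#'
#' @param cor output of \code{\link{correlationWithP}} (list with \code{r},
#'   \code{p}), or a correlation matrix (then \code{p} must be given)
#' @param p p-value matrix when \code{cor} is a plain matrix
#' @param r_pos,r_neg positive / negative correlation thresholds (default 0.8)
#' @param alpha significance level for both gates (default 0.01)
#' @param max_iter growth/prune iteration cap (default 100)
#' @return a \code{\link{CovariationResult}} (PC variance slots empty; see
#'   \code{\link{covariationAnalysis}})
#' @export
extractOpposingSubset <- function(cor, p = NULL, r_pos = 0.8, r_neg = 0.8,
                                  alpha = 0.01, max_iter = 100) {
  if (is.list(cor) && !is.null(cor$r)) { p <- cor$p; r <- cor$r } else r <- as.matrix(cor)
  if (is.null(p)) stop("p-value matrix required")
  if (!isTRUE(all.equal(dim(r), dim(p))) || nrow(r) != ncol(r))
    stop("correlation and p matrices must be square and conformable")
  ids <- rownames(r)
  if (is.null(ids)) ids <- rownames(r) <- colnames(r) <- sprintf("r%05d", seq_len(nrow(r)))
  ok <- !is.na(r) & !is.na(p)
  posM <- ok & p <= alpha & r >= r_pos; diag(posM) <- FALSE
  negM <- ok & p <= alpha & r <= -r_neg
  emptyResult <- function() {
    warning("no significant negative correlation pair; returning empty subset")
    methods::new("CovariationResult", selectedIds = character(0),
                 clusterLabel = factor(character(0), levels = c("A", "B")),
                 partner = character(0), partnerR = numeric(0),
                 pcVarianceFull = numeric(0), pcVarianceSubset = numeric(0),
                 factorAssociation = numeric(0))
  }
  if (!any(negM)) return(emptyResult())
  ## seed: most negative significant pair; ties resolved lexicographically
  rNeg <- ifelse(negM, r, NA)
  minR <- min(rNeg, na.rm = TRUE)
  cand <- which(rNeg <= minR + 1e-15, arr.ind = TRUE)
  pairIds <- t(apply(cand, 1, function(ij) sort(ids[ij])))
  o <- order(pairIds[, 1], pairIds[, 2])
  seedA <- pairIds[o[1], 1]; seedB <- pairIds[o[1], 2]
  lab <- stats::setNames(rep(NA_character_, length(ids)), ids)
  lab[seedA] <- "A"; lab[seedB] <- "B"
  for (iter in seq_len(max_iter + 1)) {
    if (iter > max_iter) stop("opposing-subset growth failed to converge")
    inA <- ids[!is.na(lab) & lab == "A"]; inB <- ids[!is.na(lab) & lab == "B"]
    free <- ids[is.na(lab)]
    if (!length(free)) break
    posA <- rowSums(posM[free, inA, drop = FALSE]) > 0
    posB <- rowSums(posM[free, inB, drop = FALSE]) > 0
    negA <- rowSums(negM[free, inA, drop = FALSE]) > 0
    negB <- rowSums(negM[free, inB, drop = FALSE]) > 0
    toA <- posA & negB; toB <- posB & negA
    both <- toA & toB
    if (any(both)) {
      bestA <- apply(ifelse(posM[free[both], inA, drop = FALSE],
                            r[free[both], inA, drop = FALSE], -Inf), 1, max)
      bestB <- apply(ifelse(posM[free[both], inB, drop = FALSE],
                            r[free[both], inB, drop = FALSE], -Inf), 1, max)
      toB[both] <- bestB > bestA
      toA[both] <- !toB[both]
    }
    if (!any(toA) && !any(toB)) break
    lab[free[toA]] <- "A"; lab[free[toB]] <- "B"
  }
  ## prune to the subset invariant: within-cluster positive and cross-cluster
  ## negative qualifying partners for every member
  for (iter in seq_len(max_iter)) {
    inA <- ids[!is.na(lab) & lab == "A"]; inB <- ids[!is.na(lab) & lab == "B"]
    sel <- c(inA, inB)
    if (!length(inA) || !length(inB)) { lab[] <- NA; break }
    keep <- vapply(seq_along(sel), function(i) {
      same <- if (lab[sel[i]] == "A") inA else inB
      other <- if (lab[sel[i]] == "A") inB else inA
      any(posM[sel[i], setdiff(same, sel[i])]) && any(negM[sel[i], other])
    }, logical(1))
    if (all(keep)) break
    lab[sel[!keep]] <- NA
  }
  sel <- ids[!is.na(lab)]
  if (!length(sel)) return(emptyResult())
  ## most anti-correlated partner over the whole analyzed set
  rr <- r; diag(rr) <- NA
  pidx <- apply(rr[sel, , drop = FALSE], 1, which.min)
  partner <- stats::setNames(ids[pidx], sel)
  partnerR <- stats::setNames(rr[cbind(sel, ids[pidx])], sel)
  methods::new("CovariationResult", selectedIds = sel,
               clusterLabel = factor(lab[sel], levels = c("A", "B")),
               partner = partner, partnerR = partnerR,
               pcVarianceFull = numeric(0), pcVarianceSubset = numeric(0),
               factorAssociation = numeric(0))
}

#' PCA variance fractions and factor association
#'
#' PCA in sample space of the row-centred log2 enrichment matrix (rows are
#' centred, not scaled, so high-variance peaks keep their influence).
#' Returns per-component variance fractions, PC1 sample scores, and p-values
#' for association of the PC1 scores with metadata factors: one-way ANOVA
#' for \code{group} and \code{litter}, correlation test for
#' \code{library_total}.
#'
#' @param x a normalized \code{EnrichmentMatrix} or log2 matrix
#' @param subset optional region ids to restrict to
#' @param meta optional data.frame with per-sample columns \code{group},
#'   \code{litter}, \code{library_total}
#' @return list with \code{var_frac}, \code{scores} (PC1 per sample) and
#'   \code{association} (named p-values)
#' @export
pcaVariance <- function(x, subset = NULL, meta = NULL) {
  m <- if (methods::is(x, "EnrichmentMatrix")) enrichValues(x) else as.matrix(x)
  if (!is.null(subset)) m <- m[subset, , drop = FALSE]
  if (ncol(m) < 2) stop("need at least two samples")
  xc <- m - rowMeans(m)
  sv <- svd(xc, nu = 0, nv = min(dim(xc)))
  lam <- sv$d^2
  varFrac <- lam / sum(lam)
  scores <- stats::setNames(sv$v[, 1] * sv$d[1], colnames(m))
  assoc <- numeric(0)
  if (!is.null(meta)) {
    if (!is.null(meta$group) && length(unique(meta$group)) > 1)
      assoc["group"] <- summary(stats::aov(scores ~ factor(meta$group)))[[1]][1, "Pr(>F)"]
    if (!is.null(meta$litter) && length(unique(meta$litter)) > 1)
      assoc["litter"] <- summary(stats::aov(scores ~ factor(meta$litter)))[[1]][1, "Pr(>F)"]
    if (!is.null(meta$library_total))
      assoc["library_total"] <- stats::cor.test(scores, meta$library_total)$p.value
  }
  list(var_frac = varFrac, scores = scores, association = assoc)
}

#' Full covariation analysis
#'
#' Convenience wrapper chaining \code{\link{topVariable}},
#' \code{\link{correlationWithP}}, \code{\link{extractOpposingSubset}} and
#' \code{\link{pcaVariance}} (full set and extracted subset) into a completed
#' \code{\link{CovariationResult}}.
#'
#' @param x a normalized \code{EnrichmentMatrix}
#' @param meta optional per-sample metadata (see \code{\link{pcaVariance}});
#'   taken from \code{colData(x)} when NULL
#' @param k number of most-variable regions to correlate (default 1000)
#' @param r_pos,r_neg,alpha thresholds for \code{\link{extractOpposingSubset}}
#' @param method correlation method
#' @return a \code{\link{CovariationResult}} with PC variance slots filled
#' @export
covariationAnalysis <- function(x, meta = NULL, k = 1000, r_pos = 0.8,
                                r_neg = 0.8, alpha = 0.01,
                                method = "pearson") {
  stopifnot(methods::is(x, "EnrichmentMatrix"))
  if (is.null(meta)) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    if (ncol(cd)) meta <- cd
  }
  k <- min(k, nrow(x))
  top <- topVariable(x, k)
  cw <- correlationWithP(x, subset = top, method = method)
  res <- suppressWarnings(extractOpposingSubset(cw, r_pos = r_pos,
                                                r_neg = r_neg, alpha = alpha))
  pcFull <- pcaVariance(x, meta = meta)
  res@pcVarianceFull <- pcFull$var_frac
  res@factorAssociation <- pcFull$association
  if (length(selectedIds(res)))
    res@pcVarianceSubset <- pcaVariance(x, subset = selectedIds(res))$var_frac
  methods::validObject(res)
  res
}

#' Export a heatmap-ready matrix of the covariation subset
#'
#' Rows ordered cluster-A-then-B (left panel order), with the per-region
#' partner rows appended in the same order (right panel).
#'
#' @param x a normalized \code{EnrichmentMatrix}
#' @param result a \code{\link{CovariationResult}}
#' @param path optional TSV output path
#' @return invisibly, a list with \code{subset} and \code{partner} matrices
#' @export
exportCovariationMatrix <- function(x, result, path = NULL) {
  m <- enrichValues(x)
  lab <- clusterLabels(result)
  ord <- selectedIds(result)[order(lab, selectedIds(result))]
  part <- partnerMap(result)
  sub <- m[ord, , drop = FALSE]
  par <- m[part$partner[match(ord, part$region)], , drop = FALSE]
  if (!is.null(path)) {
    df <- data.frame(region = ord, cluster = as.character(lab[ord]),
                     partner = part$partner[match(ord, part$region)],
                     sub, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(subset = sub, partner = par))
}
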