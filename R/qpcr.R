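## qPCR layer: ChIP fold-enrichment QC, geNorm housekeeping stability,
## delta-delta-Ct relative expression and group statistics.
##
## Ct tables are long-format data.frames with columns sample_id, target,
## fraction (IP / input / cDNA), replicate, ct. Technical replicates are
## always averaged before any difference is taken.

.validateCtTable <- function(ct) {
  need <- c("sample_id", "target", "fraction", "replicate", "ct")
  if (!all(need %in% names(ct)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop("ct values must be positive and finite")
  ct
}

#' Read a long-format Ct table (TSV)
#'
#' @param path TSV with columns sample_id, target, fraction, replicate, ct
#' @return validated data.frame
#' @export
readCtTable <- function(path) {
  .validateCtTable(utils::read.table(path, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE))
}

## replicate-averaged Ct per (sample, target, fraction)
.meanCt <- function(ct) {
  agg <- stats::aggregate(ct$ct,
                          by = list(sample_id = ct$sample_id, target = ct$target,
                                    fraction = ct$fraction), FUN = mean)
  names(agg)[4] <- "ct"
  agg
}

#' ChIP fold enrichment from Ct quartets
#'
#' FE = 2^(Ct_input - Ct_IP at the positive locus) / 2^(Ct_input - Ct_IP at
#' the negative locus), computed per sample after replicate averaging.
#' Samples with FE above \code{fe_gate} pass QC (the gate used to admit
#' ChIP samples to library preparation).
#'
#' @param ct a Ct table containing IP and input rows for both loci
#' @param pos_locus,neg_locus target names of the positive / negative control
#'   locus
#' @param fe_gate QC threshold (default 25)
#' @return data.frame with sample_id, dct_pos, dct_neg, fe, pass
#' @export
foldEnrichment <- function(ct, pos_locus, neg_locus, fe_gate = 25) {
  ct <- .validateCtTable(ct)
  m <- .meanCt(ct[ct$target %in% c(pos_locus, neg_locus), , drop = FALSE])
  samples <- sort(unique(m$sample_id))
  getCt <- function(s, tgt, frac) {
    v <- m$ct[m$sample_id == s & m$target == tgt & m$fraction == frac]
    if (length(v) != 1)
      stop(sprintf("missing %s Ct for sample '%s', locus '%s'", frac, s, tgt))
    v
  }
  out <- do.call(rbind, lapply(samples, function(s) {
    dpos <- getCt(s, pos_locus, "input") - getCt(s, pos_locus, "IP")
    dneg <- getCt(s, neg_locus, "input") - getCt(s, neg_locus, "IP")
    data.frame(sample_id = s, dct_pos = dpos, dct_neg = dneg,
               fe = 2^dpos / 2^dneg)
  }))
  out$pass <- out$fe > fe_gate
  out
}

#' geNorm stability of candidate housekeeping genes
#'
#' For gene j, \eqn{M_j} is the mean over the other candidates k of the
#' standard deviation across samples of log2(q_j / q_k), with relative
#' quantities q = 2^-Ct (so the pairwise log-ratio is Ct_k - Ct_j). The CV is
#' the coefficient of variation of each gene's normalized relative quantity
#' q_j / NF (NF = geometric mean of the candidate quantities per sample),
#' reported as the maximum over genes; normalizing by NF removes shared
#' per-sample loading, so perfectly parallel genes score CV = 0.
#'
#' @param ct Ct table (rows for the candidate genes; \code{fraction}
#'   filtered to \code{fraction} if present)
#' @param candidates character vector of at least 2 candidate gene names
#' @param fraction which fraction to use (default "cDNA")
#' @param M_max,CV_max acceptance gates (defaults 0.5 and 0.25)
#' @return list with \code{M} (named per gene), \code{CV}, and \code{pass}
#'   (all M < M_max and CV < CV_max)
#' @export
genormStability <- function(ct, candidates, fraction = "cDNA",
                            M_max = 0.5, CV_max = 0.25) {
  ct <- .validateCtTable(ct)
  if (length(candidates) < 2) stop("need at least 2 candidate genes")
  sub <- ct[ct$target %in% candidates & ct$fraction == fraction, , drop = FALSE]
  m <- .meanCt(sub)
  wide <- tapply(m$ct, list(m$sample_id, m$target), mean)
  wide <- wide[, candidates, drop = FALSE]
  if (any(is.na(wide))) stop("every candidate gene needs a Ct in every sample")
  if (nrow(wide) < 3) stop("need at least 3 samples")
  M <- vapply(candidates, function(j) {
    others <- setdiff(candidates, j)
    mean(vapply(others, function(k) stats::sd(wide[, k] - wide[, j]), numeric(1)))
  }, numeric(1))
  nf <- 2^(-rowMeans(wide))
  nrq <- 2^(-wide) / nf
  cvPerGene <- apply(nrq, 2, function(x) stats::sd(x) / mean(x))
  cv <- max(cvPerGene)
  list(M = M, CV = cv, CV_per_gene = cvPerGene,
       pass = all(M < M_max) && cv < CV_max)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample: dCt = Ct_target - mean(Ct over housekeepers) after replicate
#' averaging; ddCt = dCt - mean(dCt over the reference group); relative
#' expression = 2^-ddCt (amplification efficiency fixed at 2). Group
#' fold-changes are geometric means of the relative expression within each
#' group. Housekeeper stability is checked with
#' \code{\link{genormStability}}; failure is a warning plus a QC flag, not an
#' error.
#'
#' @param ct Ct table (fraction "cDNA")
#' @param targets character vector of target genes
#' @param housekeepers character vector of housekeeping genes (>= 1; the
#'   stability gate needs >= 2)
#' @param group named character/factor: sample_id -> group
#' @param reference_group the calibrator group (default "CTRL")
#' @return list with \code{samples} (per-sample ddCt and rel_expr),
#'   \code{group_fc} (per target, geometric-mean fold-change by group) and
#'   \code{qc} (stability report)
#' @export
ddctExpression <- function(ct, targets, housekeepers, group,
                           reference_group = "CTRL") {
  ct <- .validateCtTable(ct)
  m <- .meanCt(ct[ct$fraction == "cDNA", , drop = FALSE])
  samples <- sort(unique(m$sample_id))
  grp <- group[samples]
  if (!any(grp == reference_group)) stop("reference group is empty")
  qc <- if (length(housekeepers) >= 2 && length(samples) >= 3)
    genormStability(ct, housekeepers)
  else list(M = NA, CV = NA, pass = NA)
  if (isFALSE(qc$pass))
    warning("housekeeping genes fail the stability gates (M < 0.5, CV < 0.25)")
  hk <- m[m$target %in% housekeepers, , drop = FALSE]
  hkMean <- tapply(hk$ct, hk$sample_id, mean)
  rows <- do.call(rbind, lapply(targets, function(tg) {
    tm <- m[m$target == tg, , drop = FALSE]
    dct <- stats::setNames(tm$ct - hkMean[tm$sample_id], tm$sample_id)
    refMean <- mean(dct[names(dct)[grp[names(dct)] == reference_group]])
    ddct <- dct - refMean
    data.frame(sample_id = names(dct), gene = tg,
               group = unname(grp[names(dct)]),
               dct = unname(dct), ddct = unname(ddct),
               rel_expr = 2^(-unname(ddct)),
               qc_pass = qc$pass, row.names = NULL)
  }))
  fc <- stats::aggregate(rows$rel_expr, by = list(gene = rows$gene, group = rows$group),
                         FUN = geomMean)
  names(fc)[3] <- "fold_change"
  list(samples = rows, group_fc = fc, qc = qc)
}

#' One-way ANOVA with Fisher's LSD post-hoc comparisons
#'
#' Fixed-effects one-way ANOVA of per-sample measurements on a grouping
#' factor, followed by all pairwise Fisher LSD tests using the pooled error
#' mean square (t on N - G degrees of freedom). With two groups, F equals
#' t-squared and the LSD p-value equals the pooled t-test p-value.
#'
#' @param values numeric vector of per-sample measurements
#' @param group group labels, one per value (>= 2 groups, each >= 2 samples)
#' @param log_transform analyze log(values) instead (default FALSE)
#' @return list with \code{F}, \code{p}, \code{df}, and \code{lsd}
#'   (data.frame of pairwise comparisons)
#' @export
groupStats <- function(values, group, log_transform = FALSE) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(table(group) < 2)) stop("every group needs at least 2 samples")
  if (log_transform) values <- log(values)
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  mse <- tab["Residuals", "Mean Sq"]
  dfe <- tab["Residuals", "Df"]
  means <- tapply(values, group, mean)
  ns <- table(group)
  levs <- levels(group)
  pairs <- utils::combn(levs, 2)
  lsd <- do.call(rbind, apply(pairs, 2, function(pr) {
    d <- means[[pr[1]]] - means[[pr[2]]]
    se <- sqrt(mse * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    tt <- d / se
    data.frame(group1 = pr[1], group2 = pr[2], diff = d, t = tt,
               p = 2 * stats::pt(-abs(tt), dfe), row.names = NULL)
  }))
  list(F = tab["group", "F value"], p = tab["group", "Pr(>F)"],
       df = c(tab["group", "Df"], dfe), lsd = lsd)
}
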