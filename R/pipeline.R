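## End-to-end orchestration over synthetic or user data. No new computation
## lives here: each stage is one exported function from the other modules.

#' Run the full analysis pipeline on a simulated study
#'
#' simulate -> annotate -> blacklist filter -> normalize -> variability +
#' covariation -> peak-level NB differential enrichment with post-filters ->
#' qPCR layer, returning (and optionally writing) a machine-readable summary.
#' All thresholds are echoed into the summary so a run is fully
#' reproducible from it plus the seed.
#'
#' @param config a \code{\link{simConfig}}
#' @param outdir optional output directory; when given, the annotated peak
#'   table, covariation subset, DE table and \code{summary.json} are written
#' @param top_k most-variable regions for the correlation analysis
#' @param r_pos,r_neg,alpha covariation thresholds
#' @param fdr,bias_log2_max differential-enrichment thresholds
#' @param promoter_flank promoter half-width in bases
#' @param run_windows also run the window workflow (slower; default FALSE)
#' @return list with \code{summary} (named list of key quantities) and the
#'   intermediate objects (\code{sim}, \code{peaks}, \code{covariation},
#'   \code{de}, \code{qpcr})
#' @export
runPipeline <- function(config, outdir = NULL, top_k = 1000, r_pos = 0.8,
                        r_neg = 0.8, alpha = 0.01, fdr = 0.10,
                        bias_log2_max = 1.0, promoter_flank = 1000,
                        run_windows = FALSE) {
  ann <- simulateAnnotation(config)
  sim <- simulateCounts(config, ann)
  peaks <- assignPeaks(sim$peaks, ann$tss, flank = promoter_flank)
  peaks <- subtractBlacklist(peaks, ann$blacklist)
  keep <- intersect(regionIds(sim$broad), peakIds(peaks))
  broad <- sim$broad[keep, ]
  ctx <- classifyContext(peaks, ann$annotation, flank = promoter_flank)
  norm <- normalizeLog2(broad)
  vp <- foldChangeOverMean(norm)
  cov <- covariationAnalysis(norm, meta = sim$meta, k = min(top_k, nrow(norm)),
                             r_pos = r_pos, r_neg = r_neg, alpha = alpha)
  de <- dePeakWorkflow(broad, sim$meta$group, peaks,
                       inputCounts = sim$input[keep, ],
                       fdr = fdr, bias_log2_max = bias_log2_max)
  qp <- simulateQpcr(config)
  fe <- foldEnrichment(qp$ct, qp$pos_locus, qp$neg_locus)
  expr <- ddctExpression(qp$ct, names(config$qpcr_true_fc), qp$housekeepers,
                         qp$group, reference_group = "CTRL")
  winRes <- NULL
  if (run_windows) {
    frags <- simulateFragments(sim, config, level = "broad")
    winRes <- windowWorkflow(frags, sim$meta$group, ann$seqlengths,
                             fdr = fdr, blacklist = ann$blacklist)
  }
  nBroad <- sum(!(peakIds(peaks) %in% names(subpeakParent(peaks))))
  deFinal <- de[de$final & !is.na(de$final), , drop = FALSE]
  clusterTab <- table(clusterLabels(cov))
  deGroupFc <- sim$truth$qpcr_true_fc
  fcTab <- expr$group_fc
  estFc <- stats::setNames(vapply(names(deGroupFc), function(g)
    fcTab$fold_change[fcTab$gene == g & fcTab$group == config$de_group][1],
    numeric(1)), names(deGroupFc))
  summary <- list(
    seed = config$seed,
    n_broad_peaks = nBroad,
    n_subpeaks = length(subpeakParent(peaks)),
    promoter_peak_fraction = unname(ctx$proportions["promoter"]),
    subset_size = length(selectedIds(cov)),
    cluster_sizes = as.list(stats::setNames(as.integer(clusterTab), names(clusterTab))),
    pc1_fraction_full = if (length(pcVariance(cov)$full)) pcVariance(cov)$full[1] else NA,
    pc1_fraction_subset = if (length(pcVariance(cov)$subset)) pcVariance(cov)$subset[1] else NA,
    median_fraction_within_twofold = stats::median(vp@fractionWithinTwofold),
    n_de_final = as.list(tapply(deFinal$final, deFinal$contrast, sum,
                                default = 0L)),
    bidirectional_fraction_de = S4Vectors::metadata(de)$bidirectional_fraction,
    n_window_significant = if (is.null(winRes)) NA else sum(winRes$significant),
    fe_pass = sum(fe$pass),
    qpcr_group_fc = as.list(estFc),
    thresholds = list(top_k = top_k, r_pos = r_pos, r_neg = r_neg,
                      alpha = alpha, fdr = fdr,
                      bias_log2_max = bias_log2_max,
                      promoter_flank = promoter_flank))
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    writeAnnotatedPeaks(peaks, file.path(outdir, "annotated_peaks.tsv"),
                        context = ctx$context)
    if (length(selectedIds(cov)))
      exportCovariationMatrix(norm, cov, file.path(outdir, "covariation_subset.tsv"))
    utils::write.table(as.data.frame(de), file.path(outdir, "de_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(summary = summary, sim = sim, peaks = peaks, covariation = cov,
       de = de, qpcr = list(fe = fe, expression = expr), windows = winRes)
}
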