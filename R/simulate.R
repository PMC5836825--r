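## Synthetic-data generator with ground truth.
##
## Emulates the structure of a promoter histone-mark ChIP-seq study: three
## groups of four animals, ~10^4 promoter broad peaks composed of
## nucleosome-sized sub-peaks, NB counts driven by a single latent sample
## factor loading two anti-correlated peak clusters, a small set of modestly
## up-enriched promoter peaks in one stress group, input tracks with planted
## bias, fragment files, and Ct tables for the qPCR layer. Every stochastic
## call is governed by the config seed, so outputs are reproducible
## byte-for-byte.

#' Simulation configuration
#'
#' Defaults encode the emulated study design: 3 groups (CTRL, HD, MS) of 4
#' samples, 10,000 promoter-dominated broad peaks with 2-10 nucleosome-sized
#' sub-peaks each, NB dispersion 0.05, a unit-variance latent sample factor
#' loading two 40-region clusters with +/-1 log2-unit weights, 45 regions
#' up-enriched by 0.4 log2 units in the MS group, 20 input-biased regions,
#' and qPCR targets with fold-changes 1.43 (Ddias) and 1.32 (Pip4k2a) in MS.
#'
#' @param seed integer seed (mandatory; drives every stochastic call)
#' @param n_genes number of annotated genes
#' @param bidirectional_fraction target fraction of promoter peaks sitting at
#'   bidirectional (divergent) promoters; the matching share of genes is laid
#'   out as divergent pairs with TSS separation under 1 kb
#' @param n_broad_peaks number of broad peaks
#' @param promoter_fraction fraction of peaks planted at promoters
#' @param subpeaks_per_broad integer range (length 2) of sub-peaks per broad
#'   peak
#' @param samples data.frame with columns \code{group}, \code{n}
#' @param depth expected fragments per sample over all peaks
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2)
#' @param factor_sd standard deviation of the latent sample factor
#' @param n_cluster_regions regions per opposing cluster
#' @param loading latent-factor loading in log2 units (+ for cluster A, - for B)
#' @param n_de_regions number of differentially enriched regions
#' @param de_log2fc planted log2 fold-change, applied in \code{de_group}
#' @param de_group group receiving the planted effect (default "MS")
#' @param input_bias_regions number of regions with input (copy-number) bias
#' @param input_bias_log2 log2 magnitude of the input bias
#' @param input_depth expected input fragments per region
#' @param subpeak_conc Dirichlet concentration for per-sample sub-peak shape
#'   noise (smaller = more shape variability)
#' @param low_mapq_fraction fraction of simulated fragments with mapq < 10
#' @param fragment_width simulated fragment width (default 147,
#'   nucleosome-sized)
#' @param ct_noise_sd technical Ct noise (cycles)
#' @param qpcr_true_fc named numeric of planted qPCR fold-changes in
#'   \code{de_group}
#' @param qpcr_n_per_group cDNA samples per group for the expression layer
#' @param fe_true planted ChIP fold enrichment for the FE QC quartets
#' @return a list of class \code{SimulationConfig}
#' @export
simConfig <- function(seed,
                      n_genes = 11000,
                      bidirectional_fraction = 0.10,
                      n_broad_peaks = 10000,
                      promoter_fraction = 0.90,
                      subpeaks_per_broad = c(2L, 10L),
                      samples = data.frame(group = c("CTRL", "HD", "MS"), n = 4L),
                      depth = 1.2e6,
                      dispersion = 0.05,
                      factor_sd = 1.0,
                      n_cluster_regions = 40L,
                      loading = 1.0,
                      n_de_regions = 45L,
                      de_log2fc = 0.4,
                      de_group = "MS",
                      input_bias_regions = 20L,
                      input_bias_log2 = 2.0,
                      input_depth = 30,
                      subpeak_conc = 5,
                      low_mapq_fraction = 0.05,
                      fragment_width = 147L,
                      ct_noise_sd = 0.15,
                      qpcr_true_fc = c(Ddias = 1.43, Pip4k2a = 1.32),
                      qpcr_n_per_group = 9L,
                      fe_true = 32) {
  if (missing(seed) || !is.numeric(seed)) stop("a numeric 'seed' is mandatory")
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes >= 2, cfg$bidirectional_fraction >= 0,
            cfg$bidirectional_fraction <= 1, cfg$promoter_fraction >= 0,
            cfg$promoter_fraction <= 1, cfg$n_broad_peaks > 0,
            cfg$dispersion >= 0, cfg$depth > 0,
            length(cfg$subpeaks_per_broad) == 2)
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a gene annotation, TSS set and blacklist
#'
#' Genes are laid out along one synthetic chromosome with intergenic spacing
#' of several kb; a \code{bidirectional_fraction} of genes is arranged as
#' divergent pairs with 600 bp TSS separation. Each gene gets two exons.
#' A few blacklist intervals are planted in intergenic gaps.
#'
#' @param config a \code{\link{simConfig}}
#' @return list with \code{annotation} (GRanges: gene + exon features),
#'   \code{tss} (GRanges), \code{blacklist} (GRanges) and \code{seqlengths}
#' @export
simulateAnnotation <- function(config) {
  set.seed(config$seed)
  nG <- config$n_genes
  ## one peak serves a shared divergent promoter, so to make a fraction f of
  ## promoter peaks bidirectional, f/(1+f) of peak anchors must be pairs
  nPair <- round(nG * config$bidirectional_fraction /
                   (1 + config$bidirectional_fraction))
  nSingle <- nG - 2L * nPair
  units <- sample(c(rep("pair", nPair), rep("single", nSingle)))
  ## 8 kb between gene units leaves room for intergenic peaks clear of
  ## promoters and gene bodies
  geneLen <- 2000L; gap <- 8000L; pairSep <- 600L
  cursor <- 10000L
  starts <- ends <- integer(0); strands <- character(0); anchor <- logical(0)
  ## anchor-eligible genes (one per divergent pair) keep planted peaks
  ## non-overlapping: max peak width 1.5 kb vs >= 6 kb between anchors
  for (u in units) {
    if (u == "single") {
      starts <- c(starts, cursor); ends <- c(ends, cursor + geneLen - 1L)
      strands <- c(strands, if (stats::runif(1) < 0.5) "+" else "-")
      anchor <- c(anchor, TRUE)
      cursor <- cursor + geneLen + gap
    } else {
      ## divergent pair: minus-strand gene then plus-strand gene, TSSs 600 bp apart
      starts <- c(starts, cursor); ends <- c(ends, cursor + geneLen - 1L)
      strands <- c(strands, "-")
      s2 <- cursor + geneLen - 1L + pairSep
      starts <- c(starts, s2); ends <- c(ends, s2 + geneLen - 1L)
      strands <- c(strands, "+")
      anchor <- c(anchor, TRUE, FALSE)
      cursor <- s2 + geneLen + gap
    }
  }
  seqlen <- cursor + 10000L
  ids <- sprintf("gene%05d", seq_along(starts))
  genes <- GenomicRanges::GRanges("chrS", IRanges::IRanges(starts, ends),
                                  strand = strands)
  genes$type <- "gene"; genes$gene_id <- ids; genes$gene_name <- ids
  mkExon <- function(off1, off2) {
    e <- GenomicRanges::GRanges("chrS", IRanges::IRanges(starts + off1, starts + off2),
                                strand = strands)
    e$type <- "exon"; e$gene_id <- ids; e$gene_name <- ids
    e
  }
  ann <- c(genes, mkExon(0L, 399L), mkExon(geneLen - 200L, geneLen - 1L))
  GenomeInfoDb::seqlengths(ann) <- c(chrS = seqlen)
  tss <- .tssFromAnnotation(genes)
  blStarts <- as.integer(stats::quantile(seq_len(seqlen), probs = c(.13, .37, .58, .77, .93)))
  ## nudge blacklist intervals into intergenic gaps
  bl <- GenomicRanges::GRanges("chrS", IRanges::IRanges(blStarts, width = 1000L))
  hit <- GenomicRanges::countOverlaps(bl,
    GenomicRanges::resize(genes, GenomicRanges::width(genes) + 3000L, fix = "center")) > 0
  bl <- bl[!hit]
  list(annotation = ann, tss = tss, blacklist = bl,
       anchor_genes = ids[anchor], seqlengths = c(chrS = seqlen))
}

## positions guaranteed intergenic (away from gene bodies and promoters)
.intergenicPositions <- function(ann, seqlen, n, margin = 2500L) {
  genes <- ann[ann$type == "gene"]
  wide <- GenomicRanges::reduce(GenomicRanges::resize(
    genes, GenomicRanges::width(genes) + 2L * margin, fix = "center"))
  gaps <- GenomicRanges::gaps(GenomicRanges::GRanges("chrS",
    IRanges::ranges(wide), seqlengths = c(chrS = seqlen)))
  gaps <- gaps[GenomicRanges::width(gaps) > 2000 &
                 as.character(GenomicRanges::strand(gaps)) == "*"]
  if (n > length(gaps))
    stop("genome too small: not enough intergenic gaps for ", n, " peaks")
  ## one peak per gap so planted peaks never overlap each other
  pick <- sample(length(gaps), n)
  GenomicRanges::start(gaps)[pick] +
    floor(stats::runif(n) * (GenomicRanges::width(gaps)[pick] - 1500)) + 750L
}

#' Simulate peak architecture and NB count matrices with ground truth
#'
#' Broad peaks are planted at promoters (a \code{promoter_fraction} of them;
#' the rest intergenic), each tiled by 150-bp nucleosome-sized sub-peaks.
#' Counts follow \eqn{\log_2 \mu_{is} = b_i + \lambda_i f_s + \delta_i
#' [s \in de\_group] + \log_2 c_s} with NB sampling at dispersion alpha, and
#' sub-peak counts are a Dirichlet-multinomial split of the broad count
#' (shape noise at fixed totals). Input coverage is flat except at planted
#' biased regions, which also receive a matching apparent ChIP fold-change
#' (a copy-number-like artifact the input-bias filter must catch).
#'
#' @param config a \code{\link{simConfig}}
#' @param ann output of \code{\link{simulateAnnotation}}
#' @param subpeaks generate the sub-peak resolution (default TRUE; skipping
#'   it speeds up large simulation batteries that only need broad counts)
#' @return list with \code{peaks} (PeakSet, broad + sub-peaks), \code{broad},
#'   \code{nucleosome} (NULL when \code{subpeaks = FALSE}) and \code{input}
#'   \code{EnrichmentMatrix} objects, \code{meta} (sample data.frame) and
#'   \code{truth} (ground-truth list)
#' @export
simulateCounts <- function(config, ann, subpeaks = TRUE) {
  set.seed(config$seed + 1L)
  nP <- config$n_broad_peaks
  tss <- ann$tss
  eligible <- if (!is.null(ann$anchor_genes))
    which(tss$gene_id %in% ann$anchor_genes) else seq_along(tss)
  nProm <- min(round(nP * config$promoter_fraction), length(eligible))
  promIdx <- eligible[sample(length(eligible), nProm)]
  nRest <- nP - nProm
  centers <- GenomicRanges::start(tss)[promIdx]
  if (nRest > 0)
    centers <- c(centers, .intergenicPositions(ann$annotation,
                                               ann$seqlengths[["chrS"]], nRest))
  kSub <- sample(config$subpeaks_per_broad[1]:config$subpeaks_per_broad[2],
                 nP, replace = TRUE)
  widths <- kSub * 150L
  bStart <- pmax(1L, as.integer(centers - floor(widths / 2)))
  bEnd <- bStart + widths - 1L
  broadIds <- sprintf("bpk_%05d", seq_len(nP))
  broadGr <- GenomicRanges::GRanges("chrS", IRanges::IRanges(bStart, bEnd))
  broadGr$peak_id <- broadIds
  broadGr$score <- 100
  broadGr$q_value <- 1e-4
  ## sub-peak tiling
  subGr <- NULL; parentMap <- character(0)
  subStarts <- unlist(lapply(seq_len(nP), function(i)
    bStart[i] + 150L * (seq_len(kSub[i]) - 1L)))
  subParent <- rep(broadIds, kSub)
  subIds <- unlist(lapply(seq_len(nP), function(i)
    sprintf("%s_s%02d", broadIds[i], seq_len(kSub[i]))))
  subGr <- GenomicRanges::GRanges("chrS", IRanges::IRanges(subStarts, subStarts + 149L))
  subGr$peak_id <- subIds; subGr$score <- 100; subGr$q_value <- 1e-4
  parentMap <- stats::setNames(subParent, subIds)
  peaks <- PeakSet(c(broadGr, subGr), subpeakParent = parentMap)
  ## sample sheet
  meta <- do.call(rbind, lapply(seq_len(nrow(config$samples)), function(i)
    data.frame(group = config$samples$group[i],
               n = seq_len(config$samples$n[i]))))
  meta <- data.frame(sample_id = sprintf("%s_%d", meta$group, meta$n),
                     group = meta$group,
                     litter = sprintf("L%d", meta$n))
  nS <- nrow(meta)
  ## special region sets (disjoint, all at promoter peaks)
  promPeaks <- seq_len(nProm)
  nSpecial <- 2 * config$n_cluster_regions + config$n_de_regions +
    config$input_bias_regions
  if (nSpecial > length(promPeaks))
    stop(sprintf(paste0("config plants %d special regions but only %d promoter ",
                        "peaks exist; reduce the cluster/DE/bias set sizes"),
                 nSpecial, length(promPeaks)))
  sp <- sample(promPeaks, nSpecial)
  cutA <- config$n_cluster_regions
  clA <- sp[seq_len(cutA)]
  clB <- sp[cutA + seq_len(config$n_cluster_regions)]
  deIdx <- sp[2 * cutA + seq_len(config$n_de_regions)]
  biasIdx <- sp[2 * cutA + config$n_de_regions + seq_len(config$input_bias_regions)]
  ## log-mean model
  b <- stats::rnorm(nP, log2(config$depth / nP), 1.0)
  lambda <- numeric(nP); lambda[clA] <- config$loading; lambda[clB] <- -config$loading
  f <- stats::rnorm(nS, 0, config$factor_sd)
  cS <- 2^stats::rnorm(nS, 0, 0.25)
  cS <- cS / geomMean(cS)
  delta <- numeric(nP)
  delta[deIdx] <- config$de_log2fc
  delta[biasIdx] <- config$input_bias_log2
  inDe <- as.numeric(meta$group == config$de_group)
  log2mu <- outer(b, rep(1, nS)) + outer(lambda, f) + outer(delta, inDe) +
    outer(rep(1, nP), log2(cS))
  mu <- 2^log2mu
  counts <- if (config$dispersion > 0)
    matrix(stats::rnbinom(nP * nS, mu = mu, size = 1 / config$dispersion), nP, nS)
  else matrix(stats::rpois(nP * nS, lambda = mu), nP, nS)
  dimnames(counts) <- list(broadIds, meta$sample_id)
  meta$library_total <- colSums(counts)
  broadEm <- EnrichmentMatrix(counts, resolution = "broad", sampleMeta = meta,
                              rowRanges = stats::setNames(broadGr, broadIds))
  ## Dirichlet-multinomial sub-peak split
  nucEm <- NULL
  if (subpeaks) {
    subCounts <- matrix(0L, length(subIds), nS,
                        dimnames = list(subIds, meta$sample_id))
    offset <- c(0L, cumsum(kSub))
    for (i in seq_len(nP)) {
      k <- kSub[i]
      rows <- offset[i] + seq_len(k)
      base <- stats::rgamma(k, shape = 2) + 1e-6
      base <- base / sum(base)
      for (s in seq_len(nS)) {
        if (counts[i, s] == 0) next
        g <- stats::rgamma(k, shape = config$subpeak_conc * base * k) + 1e-9
        subCounts[rows, s] <- stats::rmultinom(1, counts[i, s], g)
      }
    }
    nucEm <- EnrichmentMatrix(subCounts, resolution = "nucleosome",
                              sampleMeta = meta,
                              rowRanges = stats::setNames(subGr, subIds))
  }
  ## input coverage: flat, with planted group bias
  inLambda <- matrix(config$input_depth, nP, nS)
  inLambda[biasIdx, inDe == 1] <- config$input_depth * 2^config$input_bias_log2
  inputCounts <- matrix(stats::rpois(nP * nS, inLambda), nP, nS,
                        dimnames = list(broadIds, paste0("inp_", meta$sample_id)))
  inputEm <- EnrichmentMatrix(inputCounts, resolution = "broad",
                              sampleMeta = data.frame(group = meta$group))
  truth <- list(cluster_members = list(A = broadIds[clA], B = broadIds[clB]),
                de_regions = stats::setNames(rep(config$de_log2fc,
                                                 length(deIdx)), broadIds[deIdx]),
                biased_input_regions = broadIds[biasIdx],
                true_size_factors = stats::setNames(cS, meta$sample_id),
                true_sample_factor_scores = stats::setNames(f, meta$sample_id),
                promoter_peaks = broadIds[promPeaks],
                qpcr_true_fc = config$qpcr_true_fc)
  list(peaks = peaks, broad = broadEm, nucleosome = nucEm, input = inputEm,
       meta = meta, truth = truth)
}

#' Simulate per-sample fragment sets from planted counts
#'
#' For each region and sample, emits exactly the planted number of fragments
#' with midpoints uniform within the region; a \code{low_mapq_fraction} of
#' fragments receives mapping quality below 10 (the rest 10-42), so counting
#' at \code{min_mapq = 10} recovers the planted totals exactly when that
#' fraction is zero.
#'
#' @param sim output of \code{\link{simulateCounts}}
#' @param config the \code{\link{simConfig}}
#' @param level which count matrix to realize: \code{"nucleosome"} (default,
#'   if present) or \code{"broad"}
#' @param dir optional directory; when given, one BED6 file per sample is
#'   written (name = fragment id, score = mapq) and paths are returned in
#'   \code{files}
#' @return named list of fragment GRanges (one per sample), with attribute
#'   \code{"files"} when \code{dir} is given
#' @export
simulateFragments <- function(sim, config, level = c("nucleosome", "broad"),
                              dir = NULL) {
  level <- match.arg(level)
  em <- if (level == "nucleosome" && !is.null(sim$nucleosome)) sim$nucleosome
        else sim$broad
  set.seed(config$seed + 2L)
  k <- enrichValues(em)
  gr <- SummarizedExperiment::rowRanges(em)
  st <- GenomicRanges::start(gr); wd <- GenomicRanges::width(gr)
  hw <- as.integer((config$fragment_width - 1) / 2)
  out <- lapply(seq_len(ncol(k)), function(s) {
    cts <- k[, s]
    tot <- sum(cts)
    rs <- rep(st, cts); rw <- rep(wd, cts)
    mids <- rs + floor(stats::runif(tot) * rw)
    mapq <- ifelse(stats::runif(tot) < config$low_mapq_fraction,
                   sample(0:9, tot, replace = TRUE),
                   sample(10:42, tot, replace = TRUE))
    fr <- GenomicRanges::GRanges("chrS",
      IRanges::IRanges(pmax(1L, mids - hw), mids + hw))
    fr$mapq <- as.integer(mapq)
    fr
  })
  names(out) <- colnames(k)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- vapply(names(out), function(s) {
      fr <- out[[s]]
      path <- file.path(dir, paste0(s, ".bed"))
      df <- data.frame(chrom = "chrS",
                       start = GenomicRanges::start(fr) - 1L,
                       end = GenomicRanges::end(fr),
                       name = sprintf("frag_%07d", seq_along(fr)),
                       score = fr$mapq, strand = ".")
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      path
    }, character(1))
    attr(out, "files") <- files
  }
  out
}

#' Simulate a qPCR Ct table
#'
#' Emits (a) cDNA Ct rows for the target genes (planted fold-changes in the
#' \code{de_group}) and two stable housekeeping genes across
#' \code{qpcr_n_per_group} samples per group, with a shared per-sample RT
#' shift that the housekeeping normalization must remove, and (b) IP/input
#' Ct quartets at a positive and a negative control locus for each ChIP
#' sample, with planted fold enrichment \code{fe_true}. All reactions are
#' emitted in technical duplicate with N(0, ct_noise_sd) noise; at zero
#' noise the ddCt and FE layers recover the planted values exactly.
#'
#' @param config a \code{\link{simConfig}}
#' @return list with \code{ct} (long-format Ct data.frame), \code{group}
#'   (named sample_id -> group), \code{housekeepers}, \code{pos_locus},
#'   \code{neg_locus}
#' @export
simulateQpcr <- function(config) {
  set.seed(config$seed + 3L)
  groups <- config$samples$group
  nQ <- config$qpcr_n_per_group
  samples <- unlist(lapply(groups, function(g) sprintf("%s_q%02d", g, seq_len(nQ))))
  grp <- stats::setNames(rep(groups, each = nQ), samples)
  hk <- c(Hprt1 = 20, Rpl16s = 22)
  targets <- config$qpcr_true_fc
  baseT <- stats::setNames(24 + seq_along(targets), names(targets))
  shift <- stats::setNames(stats::rnorm(length(samples), 0, 0.3), samples)
  noise <- function(n) stats::rnorm(n, 0, config$ct_noise_sd)
  rows <- list()
  for (g in names(c(hk, baseT))) {
    isTarget <- g %in% names(targets)
    base <- if (isTarget) baseT[[g]] else hk[[g]]
    eff <- if (isTarget) ifelse(grp[samples] == config$de_group,
                                log2(targets[[g]]), 0) else 0
    for (rep_i in 1:2) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = samples, target = g, fraction = "cDNA", replicate = rep_i,
        ct = base - eff + shift[samples] + noise(length(samples)))
    }
  }
  ## FE quartets for the ChIP samples
  chipSamples <- sprintf("%s_%d", rep(groups, each = 4), rep(1:4, length(groups)))
  dctNeg <- 1; dctPos <- log2(config$fe_true) + dctNeg
  feBase <- data.frame(target = c("pos_ctrl", "pos_ctrl", "neg_ctrl", "neg_ctrl"),
                       fraction = c("input", "IP", "input", "IP"),
                       ct = c(25, 25 - dctPos, 26, 26 - dctNeg))
  for (s in chipSamples) for (rep_i in 1:2) {
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = s, target = feBase$target, fraction = feBase$fraction,
      replicate = rep_i, ct = feBase$ct + noise(4))
  }
  ct <- do.call(rbind, rows)
  list(ct = ct, group = grp, housekeepers = names(hk),
       pos_locus = "pos_ctrl", neg_locus = "neg_ctrl")
}

#' Write a simulated annotation as GTF
#'
#' @param ann output of \code{\link{simulateAnnotation}}
#' @param path output GTF path
#' @return invisibly, the path
#' @export
writeGtf <- function(ann, path) {
  gr <- ann$annotation
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
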