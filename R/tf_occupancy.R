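# Transcription-factor occupancy analyses: co-occupancy Venn counts,
# ROC prediction of acetylation loss from tag density, resampling-null
# gene-proximity enrichment and dex-response binning of bound enhancers.

#' Co-occupancy of peak sets over a region set
#'
#' A region is "occupied" by a factor when at least one of its peaks
#' overlaps the region by >= 1 bp.
#'
#' @param regions `genomic_intervals` table (e.g. DHSs)
#' @param peak_sets named list of `genomic_intervals` peak tables with a
#'   `score` column holding tag density
#' @return list with `table` (data.frame: region, occupancy booleans and
#'   tag density per factor) and `venn` (named counts for every factor
#'   combination; names like "GR+FOXO1")
#' @export
co_occupancy <- function(regions, peak_sets) {
  stopifnot(length(peak_sets) >= 1, !is.null(names(peak_sets)))
  n <- nrow(regions)
  occ <- matrix(FALSE, n, length(peak_sets),
                dimnames = list(regions$name, names(peak_sets)))
  dens <- matrix(0, n, length(peak_sets),
                 dimnames = dimnames(occ))
  for (f in names(peak_sets)) {
    ov <- overlap_pairs(regions, peak_sets[[f]])
    occ[unique(ov$query), f] <- TRUE
    if (nrow(ov) > 0) {
      agg <- tapply(peak_sets[[f]]$score[ov$subject], ov$query, max)
      dens[as.integer(names(agg)), f] <- agg
    }
  }
  pattern <- apply(occ, 1, function(r) {
    if (!any(r)) "none" else paste(names(peak_sets)[r], collapse = "+")
  })
  combos <- c("none", unlist(lapply(seq_along(peak_sets), function(k) {
    utils::combn(names(peak_sets), k, paste, collapse = "+")
  })))
  venn <- stats::setNames(
    vapply(combos, function(cb) sum(pattern == cb), integer(1)), combos)
  tab <- data.frame(region = regions$name, occ, dens,
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(tab) <- c("region", paste0("occ_", names(peak_sets)),
                     paste0("density_", names(peak_sets)))
  list(table = tab, venn = venn)
}

#' ROC of a score predicting a binary label
#'
#' AUC is computed through the rank (Mann-Whitney) identity
#' AUC = U / (n1 * n0) with ties averaged, which equals the trapezoidal
#' area under the ROC curve over all score thresholds.
#'
#' @param score numeric predictor per region (e.g. TF tag density)
#' @param label logical per region; TRUE = positive class (e.g.
#'   feeding-reduced H3K27Ac)
#' @return list with `auc` and `curve` (data.frame fpr, tpr)
#' @export
roc_predict <- function(score, label) {
  stopifnot(length(score) == length(label))
  label <- as.logical(label)
  n1 <- sum(label)
  n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) stop("both label classes must be non-empty")
  r <- rank(score, ties.method = "average")
  auc <- (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(-score)
  tpr <- c(0, cumsum(label[ord]) / n1)
  fpr <- c(0, cumsum(!label[ord]) / n0)
  # collapse tied thresholds to single curve points
  thr <- c(Inf, score[ord])
  keep <- c(diff(thr) != 0, TRUE)
  list(auc = auc, curve = data.frame(fpr = fpr[keep], tpr = tpr[keep]))
}

#' Resampling-null enrichment of peaks near a gene set
#'
#' The observed frequency is the fraction of genes with at least one
#' peak whose center lies within `window` bases of the gene's TSS
#' (union over the supplied peak sets). `n_random` seeded random gene
#' sets drawn without replacement from the universe give the null
#' frequencies; relative enrichment is observed / mean(null). Both a
#' two-sided one-sample t-test of the null frequencies against the
#' observed value and an empirical permutation p-value are reported.
#'
#' @param gene_set character vector of gene ids
#' @param peak_sets named list of `genomic_intervals` peak tables
#' @param universe gene annotation (`genomic_intervals` BED6, name =
#'   gene id) for all genes; TSSs are derived per strand
#' @param window distance cutoff in bases (default 50000)
#' @param n_random number of random sets (default 6)
#' @param random_size size of each random set (default: size of
#'   `gene_set`)
#' @param seed seed for the random draws
#' @return list: observed, null (vector), relative_enrichment, sem,
#'   t_p, perm_p, per_factor (observed frequency per peak set)
#' @export
proximity_enrichment <- function(gene_set, peak_sets, universe,
                                 window = 5e4, n_random = 6,
                                 random_size = length(gene_set),
                                 seed = 1L) {
  if (random_size > nrow(universe)) {
    stop("random set size exceeds the gene universe")
  }
  tss <- tss_from_genes(universe)
  centers <- lapply(peak_sets, function(p) {
    data.frame(chrom = p$chrom, center = interval_center(p))
  })
  freq <- function(genes, sets) {
    gt <- tss[tss$gene %in% genes, , drop = FALSE]
    hit <- rep(FALSE, nrow(gt))
    for (ct in sets) {
      for (chr in unique(gt$chrom)) {
        ig <- which(gt$chrom == chr)
        cc <- sort(ct$center[ct$chrom == chr])
        if (length(cc) == 0) next
        # any center in [pos - window, pos + window]
        cnt <- findInterval(gt$pos[ig] + window, cc) -
          findInterval(gt$pos[ig] - window - 1, cc)
        hit[ig] <- hit[ig] | cnt > 0
      }
    }
    mean(hit)
  }
  observed <- freq(gene_set, centers)
  per_factor <- vapply(centers, function(ct) freq(gene_set, list(ct)),
                       numeric(1))
  set.seed(seed)
  null <- vapply(seq_len(n_random), function(i) {
    freq(sample(universe$name, random_size), centers)
  }, numeric(1))
  sem <- stats::sd(null) / sqrt(n_random)
  t_p <- if (stats::sd(null) > 0) {
    stats::t.test(null, mu = observed)$p.value
  } else as.numeric(all(null == observed))
  perm_p <- min(1, 2 * min((1 + sum(null >= observed)) / (n_random + 1),
                           (1 + sum(null <= observed)) / (n_random + 1)))
  list(observed = observed, null = null,
       relative_enrichment = observed / mean(null), sem = sem,
       t_p = t_p, perm_p = perm_p, per_factor = per_factor)
}

#' Tertile binning of bound enhancers by hormone response
#'
#' GR-occupied DHSs are ranked by their dex-response log2 fold change
#' (descending) and split into `k` equal bins; the remainder goes to the
#' higher-response bins. Optional covariates (feeding log2 FC, occupancy,
#' motif score) are compared between the extreme bins with a
#' Mann-Whitney test.
#'
#' @param ids region ids
#' @param response dex log2 fold change per region
#' @param k number of bins (default 3: high / medium / low)
#' @param covariates optional named list of numeric vectors aligned with
#'   `ids`
#' @return list with `bins` (data.frame id, response, bin) and
#'   `comparisons` (per covariate: medians by bin and high-vs-low
#'   Mann-Whitney p)
#' @export
dex_response_bins <- function(ids, response, k = 3L, covariates = NULL) {
  stopifnot(length(ids) == length(response))
  n <- length(ids)
  if (n < k) stop("fewer regions than bins")
  ord <- order(-response, ids)
  base <- n %/% k
  sizes <- rep(base, k)
  rem <- n - base * k
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
  bin_idx <- rep.int(seq_len(k), sizes)
  lev <- if (k == 3) c("high", "medium", "low") else paste0("bin", 1:k)
  bins <- data.frame(id = ids[ord], response = response[ord],
                     bin = factor(lev[bin_idx], levels = lev),
                     stringsAsFactors = FALSE)
  comparisons <- NULL
  if (!is.null(covariates)) {
    comparisons <- lapply(covariates, function(v) {
      vo <- v[ord]
      hi <- vo[bin_idx == 1]
      lo <- vo[bin_idx == k]
      list(medians = tapply(vo, bins$bin, stats::median),
           high_vs_low_p = suppressWarnings(
             stats::wilcox.test(hi, lo, exact = FALSE)$p.value))
    })
  }
  list(bins = bins, comparisons = comparisons)
}
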