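# Decomposition of feeding-repressed genes into glucocorticoid (dex) and
# insulin-antagonist (S961) response clusters, PCA summaries with 0.9
# error ellipses, and resampling-null cluster enrichment.

#' Feeding-repressed genes
#'
#' @param diff differential result (log2fc = fed over unfed)
#' @param fdr_cut FDR threshold (default 0.05)
#' @return character vector of gene ids with fdr < cut and log2fc < 0
#' @export
identify_feeding_repressed <- function(diff, fdr_cut = 0.05) {
  diff$id[!is.na(diff$fdr) & diff$fdr < fdr_cut & diff$log2fc < 0]
}

#' Hormone-response cluster calls
#'
#' Each feeding-repressed gene is tested for de-repression (FDR < cut
#' and log2fc > 0 versus fed-vehicle) under dex, S961 and the
#' combination, then mapped through the decision table: neither single
#' arm nor combo -> cluster 1; dex only -> 2; S961 only -> 3; both
#' single arms -> 4; combo only -> 5. Combo significance is ignored
#' whenever a single arm is significant. Genes missing from any contrast
#' are flagged unclassified.
#'
#' @param genes feeding-repressed gene ids
#' @param diff_dex,diff_s961,diff_combo differential results of each arm
#'   versus fed-vehicle
#' @param fdr_cut FDR threshold (default 0.05)
#' @return data.frame: gene, sig_dex, sig_s961, sig_combo, cluster
#'   (1..5, NA when unclassified), unclassified
#' @export
classify_response <- function(genes, diff_dex, diff_s961, diff_combo,
                              fdr_cut = 0.05) {
  flag <- function(diff) {
    i <- match(genes, diff$id)
    sig <- !is.na(diff$fdr[i]) & diff$fdr[i] < fdr_cut &
      diff$log2fc[i] > 0
    sig[is.na(i)] <- NA
    sig
  }
  dex <- flag(diff_dex)
  s961 <- flag(diff_s961)
  combo <- flag(diff_combo)
  unclassified <- is.na(dex) | is.na(s961) | is.na(combo)
  cluster <- ifelse(dex & s961, 4L,
                    ifelse(dex, 2L,
                           ifelse(s961, 3L, ifelse(combo, 5L, 1L))))
  cluster[unclassified] <- NA_integer_
  data.frame(gene = genes, sig_dex = dex, sig_s961 = s961,
             sig_combo = combo, cluster = cluster,
             unclassified = unclassified, stringsAsFactors = FALSE)
}

#' PCA of expression profiles with per-group 0.9 error ellipses
#'
#' Samples are projected by mean-centered SVD (prcomp); for each sample
#' group, a 0.9-coverage error ellipse in the PC1-PC2 plane is derived
#' from the 2-D score covariance scaled by the chi-square 0.9 quantile
#' with 2 degrees of freedom.
#'
#' @param mat features x samples matrix (e.g. log2 normalized counts of
#'   the feeding-regulated genes)
#' @param groups group label per sample
#' @return list: scores (samples x PCs), explained (variance fractions),
#'   loadings, ellipses (per group: center, axes, angle)
#' @export
pca_summary <- function(mat, groups) {
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == length(groups))
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x
  q <- stats::qchisq(0.9, df = 2)
  ellipses <- lapply(split(seq_along(groups), groups), function(idx) {
    s2 <- scores[idx, 1:2, drop = FALSE]
    ctr <- colMeans(s2)
    if (length(idx) < 2) {
      return(list(center = ctr, axes = c(0, 0), angle = 0))
    }
    ev <- eigen(stats::cov(s2), symmetric = TRUE)
    list(center = ctr, axes = sqrt(pmax(ev$values, 0) * q),
         angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1]))
  })
  list(scores = scores, explained = explained, loadings = pc$rotation,
       ellipses = ellipses)
}

#' Resampling-null enrichment of a regulated gene set across clusters
#'
#' For each cluster, the observed fraction of members belonging to the
#' regulated set is compared with the fractions obtained for seeded
#' random gene sets of the same size drawn without replacement from the
#' supplied universe (e.g. all feeding-regulated genes).
#'
#' @param clusters data.frame with columns gene (or id) and cluster
#' @param regulated character vector of regulated gene ids
#' @param universe character vector to draw random sets from
#' @param n_random number of random sets (default 6)
#' @param seed seed for the draws
#' @return data.frame per cluster: cluster, n, observed, null_mean, sem,
#'   relative_enrichment, t_p, perm_p, flagged (TRUE for empty clusters)
#' @export
cluster_enrichment <- function(clusters, regulated, universe,
                               n_random = 6, seed = 1L) {
  id_col <- if ("gene" %in% names(clusters)) "gene" else "id"
  if (length(regulated) > length(universe)) {
    stop("regulated set larger than the universe")
  }
  set.seed(seed)
  draws <- lapply(seq_len(n_random), function(i) {
    sample(universe, length(regulated))
  })
  labs <- sort(unique(clusters$cluster))
  rows <- lapply(labs, function(cl) {
    members <- clusters[[id_col]][clusters$cluster == cl]
    if (length(members) == 0) {
      return(data.frame(cluster = cl, n = 0L, observed = NA, null_mean = NA,
                        sem = NA, relative_enrichment = NA, t_p = NA,
                        perm_p = NA, flagged = TRUE))
    }
    obs <- mean(members %in% regulated)
    null <- vapply(draws, function(d) mean(members %in% d), numeric(1))
    sem <- stats::sd(null) / sqrt(n_random)
    t_p <- if (stats::sd(null) > 0) {
      stats::t.test(null, mu = obs)$p.value
    } else as.numeric(all(null == obs))
    perm_p <- min(1, 2 * min((1 + sum(null >= obs)) / (n_random + 1),
                             (1 + sum(null <= obs)) / (n_random + 1)))
    data.frame(cluster = cl, n = length(members), observed = obs,
               null_mean = mean(null), sem = sem,
               relative_enrichment = obs / mean(null), t_p = t_p,
               perm_p = perm_p, flagged = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Clustering of lean/obese feeding profiles with per-cluster statistics
#'
#' Ward-clusters gene z-score profiles across lean/obese x fed/unfed
#' conditions into k clusters, compares lean versus obese per-gene mean
#' expression within each cluster and condition (Mann-Whitney), and
#' optionally computes dex/S961 regulated-set enrichment per cluster.
#'
#' @param zmat z-scored genes x samples matrix with `condition_repN`
#'   column names, conditions lean_fed, lean_unfed, obese_fed,
#'   obese_unfed
#' @param k number of clusters (default 8)
#' @param regulated_sets optional named list of regulated gene-id sets
#' @param universe universe for enrichment (default: all clustered
#'   genes)
#' @param n_random,seed passed to [cluster_enrichment()]
#' @return list: clusters, profiles, lean_vs_obese (per cluster x
#'   condition Mann-Whitney p), enrichment (per regulated set)
#' @export
obesity_cluster_analysis <- function(zmat, k = 8L, regulated_sets = NULL,
                                     universe = rownames(zmat),
                                     n_random = 6, seed = 1L) {
  cl <- cluster_enhancers(zmat, k)
  conds <- unique(sample_conditions(colnames(zmat)))
  lean <- grep("^lean_", conds, value = TRUE)
  comparisons <- lapply(lean, function(lc) {
    oc <- sub("^lean_", "obese_", lc)
    li <- sample_conditions(colnames(zmat)) == lc
    oi <- sample_conditions(colnames(zmat)) == oc
    vapply(seq_len(k), function(c) {
      rows <- cl$clusters$cluster == c
      suppressWarnings(stats::wilcox.test(
        rowMeans(zmat[rows, li, drop = FALSE]),
        rowMeans(zmat[rows, oi, drop = FALSE]),
        exact = FALSE)$p.value)
    }, numeric(1))
  })
  names(comparisons) <- sub("^lean_", "", lean)
  enrichment <- NULL
  if (!is.null(regulated_sets)) {
    enrichment <- lapply(regulated_sets, function(rs) {
      cluster_enrichment(
        data.frame(gene = cl$clusters$id, cluster = cl$clusters$cluster,
                   stringsAsFactors = FALSE),
        intersect(rs, universe), universe, n_random = n_random,
        seed = seed)
    })
  }
  list(clusters = cl$clusters, profiles = cl$profiles,
       lean_vs_obese = comparisons, enrichment = enrichment)
}
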