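# Enhancer activity at DNase hypersensitive sites: tag quantification in
# a centered window, differential acetylation, DNase/H3K27Ac fold-change
# coupling, TSS-distance enrichment and Ward clustering of z-profiles.

#' Quantify tags at DHSs in a centered window
#'
#' Counts tags whose position falls in the half-open window of `width`
#' bases centered on each DHS. Pre-tabulated count matrices pass through
#' unchanged.
#'
#' @param tags data.frame with columns chrom, pos (one row per tag), a
#'   named list of such data.frames (one per sample), or a pre-tabulated
#'   matrix (returned as-is)
#' @param dhs `genomic_intervals` table of DHSs
#' @param width window width in bases (default 800)
#' @return matrix of counts, DHSs x samples (single vector for one
#'   sample)
#' @export
quantify_at_dhs <- function(tags, dhs, width = 800L) {
  if (is.matrix(tags)) return(tags)
  if (is.data.frame(tags)) tags <- list(sample1 = tags)
  win <- window_around_center(dhs, width)
  counts <- vapply(tags, function(tg) {
    out <- integer(nrow(win))
    for (chr in unique(win$chrom)) {
      iw <- which(win$chrom == chr)
      pos <- tg$pos[tg$chrom == chr]
      if (length(pos) == 0) next
      # half-open window [start, end): tag at p counts iff start <= p < end
      pos <- sort(pos)
      out[iw] <- findInterval(win$end[iw] - 1L, pos) -
        findInterval(win$start[iw] - 1L, pos)
    }
    out
  }, integer(nrow(win)))
  counts <- matrix(counts, nrow = nrow(win),
                   dimnames = list(dhs$name, names(tags)))
  counts
}

#' Differential H3K27Ac at DHSs
#'
#' Delegates to [nb_wald_test()] and classifies DHSs at the FDR cut by
#' fold-change sign.
#'
#' @param counts DHS x sample count matrix
#' @param group_a,group_b sample columns (log2fc = B over A)
#' @param fdr_cut FDR threshold (default 0.1)
#' @return list with `result` (full test table), `up` and `down` (DHS
#'   ids)
#' @export
differential_acetylation <- function(counts, group_a, group_b,
                                     fdr_cut = 0.1) {
  res <- nb_wald_test(counts, group_a, group_b)
  sel <- !is.na(res$fdr) & res$fdr < fdr_cut
  list(result = res, up = res$id[sel & res$log2fc > 0],
       down = res$id[sel & res$log2fc < 0])
}

#' Pearson correlation of DNase and H3K27Ac fold changes
#'
#' @param x,y paired numeric vectors (e.g. DNase and H3K27Ac log2 FCs)
#' @param subset optional logical or index subset (e.g. differential
#'   DHSs, giving r_de as opposed to r_all)
#' @return list: r, ci (95%, Fisher z), p_value, n
#' @export
fc_correlation <- function(x, y, subset = NULL) {
  if (!is.null(subset)) {
    x <- x[subset]
    y <- y[subset]
  }
  ok <- is.finite(x) & is.finite(y)
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), ci = unname(ct$conf.int),
       p_value = ct$p.value, n = sum(ok))
}

#' TSS-distance enrichment of a focal DHS set
#'
#' Compares absolute distances to the nearest TSS between a focal and a
#' reference DHS set with a two-sample, two-sided asymptotic
#' Kolmogorov-Smirnov test, and returns the two cumulative distance
#' curves.
#'
#' @param focal,reference `genomic_intervals` tables of DHSs
#' @param tss data.frame chrom/pos (restrict to the gene set of
#'   interest's TSSs before calling)
#' @return list: ks_d, p_value, curves (data.frame distance, ecdf_focal,
#'   ecdf_reference), distances
#' @export
tss_distance_enrichment <- function(focal, reference, tss) {
  df <- abs(distance_to_nearest_tss(focal, tss)$distance)
  dr <- abs(distance_to_nearest_tss(reference, tss)$distance)
  df <- df[!is.na(df)]
  dr <- dr[!is.na(dr)]
  ks <- suppressWarnings(stats::ks.test(df, dr, exact = FALSE))
  grid <- sort(unique(c(df, dr)))
  curves <- data.frame(distance = grid,
                       ecdf_focal = stats::ecdf(df)(grid),
                       ecdf_reference = stats::ecdf(dr)(grid))
  list(ks_d = unname(ks$statistic), p_value = ks$p.value,
       curves = curves, distances = list(focal = df, reference = dr))
}

#' Ward clustering of enhancer (or gene) z-score profiles
#'
#' Agglomerative clustering with Ward linkage on Euclidean distances
#' (`hclust` method "ward.D2", i.e. Ward's criterion via Lance-Williams
#' updates on squared distances), cut at k clusters.
#'
#' @param zmat z-scored rows x conditions matrix
#' @param k number of clusters (2 <= k <= nrow)
#' @return list with `clusters` (data.frame id, cluster), `profiles`
#'   (k x conditions mean z per cluster) and the `hclust` tree
#' @export
cluster_enhancers <- function(zmat, k) {
  zmat <- as.matrix(zmat)
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(zmat)) stop("k exceeds the number of rows")
  tree <- stats::hclust(stats::dist(zmat), method = "ward.D2")
  lab <- stats::cutree(tree, k = k)
  ids <- rownames(zmat) %||% paste0("row", seq_len(nrow(zmat)))
  profiles <- t(vapply(seq_len(k), function(c) {
    colMeans(zmat[lab == c, , drop = FALSE])
  }, numeric(ncol(zmat))))
  rownames(profiles) <- paste0("cluster", seq_len(k))
  list(clusters = data.frame(id = ids, cluster = unname(lab),
                             stringsAsFactors = FALSE),
       profiles = profiles, tree = tree)
}
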