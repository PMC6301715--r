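# Shared count statistics: median-of-ratios normalization, a two-group
# negative-binomial Wald test, BH correction, RPKM and row z-scores.
#
# The NB model is parameterized by mean m and dispersion alpha with
# variance m + alpha * m^2 (rnbinom's size = 1/alpha).

#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over features of
#' count / geometric-mean-of-the-feature, computed over features with
#' strictly positive counts in every sample. Factors are rescaled so their
#' geometric mean is 1.
#'
#' @param counts feature-by-sample matrix of non-negative counts
#' @return named positive numeric vector, one factor per sample
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts > 0) == ncol(counts)
  if (!any(keep)) {
    stop("no feature has positive counts in all samples; ",
         "consider a pseudo-reference sample")
  }
  logc <- log(counts[keep, , drop = FALSE])
  ref <- rowMeans(logc)  # log geometric mean per feature
  sf <- exp(apply(logc - ref, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Reads per kilobase per million mapped reads
#'
#' rpkm_ij = count_ij * 1e9 / (length_i * libsize_j).
#'
#' @param counts feature-by-sample count matrix
#' @param lengths per-feature length in bases
#' @param libsize per-sample library size (mapped reads)
#' @return numeric matrix of RPKM values
#' @export
rpkm <- function(counts, lengths, libsize) {
  counts <- as.matrix(counts)
  if (any(lengths <= 0)) stop("feature lengths must be positive")
  if (any(libsize <= 0)) stop("library sizes must be positive")
  t(t(counts / lengths) / libsize) * 1e9
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values (NAs preserved)
#' @return BH-adjusted values
#' @export
bh_fdr <- function(p) stats::p.adjust(p, method = "BH")

#' Two-group negative-binomial Wald test
#'
#' Differential test used for both gene expression and H3K27Ac counts.
#' Counts are normalized by median-of-ratios size factors; per-feature
#' dispersion is estimated by method of moments from within-group residuals
#' and shrunk 50/50 toward a log-linear mean-dispersion trend; the Wald
#' statistic is log2 fold change over its standard error from the NB GLM
#' Fisher information, referred to a t distribution whose degrees of
#' freedom are the within-group residual df plus 8 prior df (the
#' information the mean-dispersion trend contributes); BH FDR is
#' computed over all tested features.
#'
#' Features with zero counts in every sample are excluded from testing and
#' flagged (`tested = FALSE`). A +0.5 pseudocount enters only the reported
#' log2 fold change of features with a zero group mean, never the test;
#' such features are flagged `zero_group` and get NA p-values.
#'
#' @param counts feature-by-sample count matrix with rownames
#' @param group_a,group_b column names or indices of the two groups;
#'   log2fc is group B over group A
#' @param sf optional precomputed size factors for all used samples
#' @param min_disp dispersion floor (default 1e-8)
#' @return data.frame: id, baseMean, log2fc, se, stat, pvalue, fdr,
#'   dispersion, tested, zero_group
#' @export
nb_wald_test <- function(counts, group_a, group_b, sf = NULL,
                         min_disp = 1e-8) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("feature", seq_len(nrow(counts)))
  }
  a <- .resolve_cols(counts, group_a)
  b <- .resolve_cols(counts, group_b)
  if (length(a) == 0 || length(b) == 0) stop("each group needs >= 1 sample")
  sub <- counts[, c(a, b), drop = FALSE]
  if (is.null(sf)) sf <- size_factors(sub)
  ia <- seq_along(a)
  ib <- length(a) + seq_along(b)

  z <- sweep(sub, 2, sf, "/")
  tested <- rowSums(sub) > 0
  qa <- rowMeans(z[, ia, drop = FALSE])
  qb <- rowMeans(z[, ib, drop = FALSE])
  base_mean <- rowMeans(z)

  # method-of-moments dispersion from pooled within-group variance:
  # Var(K/s) ~= mu * mean(1/s) + alpha * mu^2
  na <- length(ia); nb <- length(ib)
  ss <- rowSums((z[, ia, drop = FALSE] - qa)^2) +
    rowSums((z[, ib, drop = FALSE] - qb)^2)
  df_w <- max(na + nb - 2, 1)
  var_w <- ss / df_w
  inv_s <- mean(1 / sf)
  alpha_mom <- (var_w - base_mean * inv_s) / base_mean^2
  alpha_mom[!is.finite(alpha_mom)] <- NA

  # log-linear mean-dispersion trend over features with informative MoM
  pos <- which(tested & !is.na(alpha_mom) & alpha_mom > 0 & base_mean > 0)
  if (length(pos) >= 10) {
    fit <- stats::lm(log(alpha_mom[pos]) ~ log(base_mean[pos]))
    lx <- log(pmax(base_mean, min(base_mean[pos])))
    alpha_trend <- exp(stats::coef(fit)[1] + stats::coef(fit)[2] * lx)
  } else {
    alpha_trend <- rep(mean(alpha_mom[pos]) %||% 0.1, nrow(sub))
    if (!length(pos)) alpha_trend <- rep(0.1, nrow(sub))
  }
  alpha_trend <- pmin(pmax(alpha_trend, min_disp), 10)
  disp <- 0.5 * pmax(alpha_mom, 0, na.rm = FALSE) + 0.5 * alpha_trend
  disp[is.na(alpha_mom)] <- alpha_trend[is.na(alpha_mom)]
  disp <- pmin(pmax(disp, min_disp), 10)

  zero_group <- tested & (qa == 0 | qb == 0)
  ok <- tested & !zero_group

  log2fc <- rep(NA_real_, nrow(sub))
  log2fc[ok] <- log2(qb[ok] / qa[ok])
  log2fc[zero_group] <- log2((qb[zero_group] + 0.5) / (qa[zero_group] + 0.5))

  # Wald SE from Fisher information of the log-link NB GLM per group
  info <- function(q, idx) {
    mu <- outer(q, sf[idx])  # features x samples expected counts
    rowSums(mu / (1 + disp * mu))
  }
  se <- rep(NA_real_, nrow(sub))
  se[ok] <- sqrt(1 / info(qa, ia)[ok] + 1 / info(qb, ib)[ok]) / log(2)
  stat <- log2fc / se
  # moderation-style df augmentation: the trend blend contributes prior
  # information on the dispersion, so the reference t gets
  # residual df + 8 prior df rather than the residual df alone
  pvalue <- 2 * stats::pt(-abs(stat), df = df_w + 8)
  pvalue[!ok] <- NA
  fdr <- rep(NA_real_, nrow(sub))
  fdr[ok] <- bh_fdr(pvalue[ok])

  data.frame(id = rownames(sub), baseMean = base_mean, log2fc = log2fc,
             se = se, stat = stat, pvalue = pvalue, fdr = fdr,
             dispersion = disp, tested = tested, zero_group = zero_group,
             row.names = NULL, stringsAsFactors = FALSE)
}

.resolve_cols <- function(counts, idx) {
  if (is.character(idx)) {
    miss <- setdiff(idx, colnames(counts))
    if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
    match(idx, colnames(counts))
  } else as.integer(idx)
}

#' Row-wise z-score transform
#'
#' Each row gets its mean subtracted and is divided by its sample standard
#' deviation (n - 1 denominator). Constant rows become all-zero and are
#' flagged in the `"constant"` attribute.
#'
#' @param m numeric matrix
#' @return matrix of the same shape with attribute `constant` (logical
#'   per row)
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  constant <- sd == 0 | is.na(sd)
  out <- (m - mu) / ifelse(constant, 1, sd)
  out[constant, ] <- 0
  attr(out, "constant") <- constant
  out
}

#' Write a differential-test result table as TSV
#'
#' @param res result of [nb_wald_test()]
#' @param path output path
#' @export
write_differential <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
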