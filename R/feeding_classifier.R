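# Classification of circadian genes by feeding dependence: FDR selection,
# quintile binning on the ZT10 vs ZT14-unfed fold change, cosinor phase
# estimation and per-bin average z-score profiles.

#' Select feeding-regulated genes from a differential result
#'
#' @param diff result of [nb_wald_test()] (log2fc = ZT14-fed over ZT10)
#' @param fdr_cut FDR threshold (default 0.01)
#' @return list with character vectors `induced` (log2fc > 0) and
#'   `repressed` (log2fc < 0)
#' @export
select_regulated <- function(diff, fdr_cut = 0.01) {
  ok <- !is.na(diff$fdr) & diff$fdr < fdr_cut
  list(induced = diff$id[ok & diff$log2fc > 0],
       repressed = diff$id[ok & diff$log2fc < 0])
}

#' Quintile binning by feeding dependence
#'
#' Genes are ranked by the absolute log2 fold change between ZT10 and
#' ZT14-unfed — the expression change that persists without food. Q1
#' holds the largest persistent changes (feeding-independent,
#' clock-driven behavior); Q5 the smallest (the ZT10 to ZT14 change
#' requires food). Bin sizes differ by at most one, with the remainder
#' going to the lower-index bins; ties are broken by gene id.
#'
#' @param genes character vector of gene ids
#' @param stat ranking statistic per gene: log2fc of ZT10 vs ZT14-unfed
#'   (absolute value is used)
#' @param direction optional direction label carried through
#' @param n_bins number of bins (default 5)
#' @return data.frame: gene, direction, bin ("Q1".."Q5"), stat
#' @export
quintile_bin <- function(genes, stat, direction = NA_character_,
                         n_bins = 5L) {
  stopifnot(length(genes) == length(stat))
  if (length(genes) < n_bins) {
    stop("need at least ", n_bins, " genes to form ", n_bins, " bins")
  }
  ord <- order(-abs(stat), genes)
  n <- length(genes)
  base <- n %/% n_bins
  sizes <- rep(base, n_bins)
  rem <- n - base * n_bins
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
  bin <- rep.int(seq_len(n_bins), sizes)
  out <- data.frame(gene = genes[ord],
                    direction = rep_len(direction, n),
                    bin = paste0("Q", bin), stat = stat[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Circadian phase by cosinor fit
#'
#' Least-squares fit of y = m + a * cos(2*pi*(t - phi) / 24) per gene via
#' the linear reparameterization in cos and sin. A gene is called
#' rhythmic when the fitted amplitude exceeds `rhythm_threshold` times
#' the residual standard deviation; phase is reported only for rhythmic
#' genes.
#'
#' @param series genes x timepoints matrix
#' @param timepoints sampling times in hours (>= 4 points spanning >= 12 h)
#' @param rhythm_threshold amplitude/noise ratio for the rhythmic call
#'   (default 2)
#' @return data.frame: gene, phase (hours in [0, 24)), amplitude,
#'   rhythmic
#' @export
assign_phase <- function(series, timepoints, rhythm_threshold = 2) {
  series <- as.matrix(series)
  stopifnot(ncol(series) == length(timepoints))
  if (length(timepoints) < 4 || diff(range(timepoints)) < 12) {
    stop("need >= 4 timepoints spanning >= 12 h")
  }
  xc <- cos(2 * pi * timepoints / 24)
  xs <- sin(2 * pi * timepoints / 24)
  xmat <- cbind(1, xc, xs)
  coefs <- t(solve(crossprod(xmat), crossprod(xmat, t(series))))
  fitted <- xmat %*% t(coefs)
  dfree <- max(length(timepoints) - 3, 1)
  rsd <- sqrt(colSums((t(series) - fitted)^2) / dfree)
  amp <- sqrt(coefs[, 2]^2 + coefs[, 3]^2)
  phase <- (atan2(coefs[, 3], coefs[, 2]) * 24 / (2 * pi)) %% 24
  rhythmic <- rsd > 0 & amp > rhythm_threshold * rsd
  data.frame(gene = rownames(series) %||%
               paste0("gene", seq_len(nrow(series))),
             phase = ifelse(rhythmic, phase, NA_real_),
             amplitude = amp, rhythmic = rhythmic,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Average z-score profile per quintile bin
#'
#' @param zmat z-scored genes x timepoints (or conditions) matrix
#' @param assignment output of [quintile_bin()]
#' @return bins x columns matrix of mean member z-scores
#' @export
bin_profile <- function(zmat, assignment) {
  stopifnot(all(assignment$gene %in% rownames(zmat)))
  bins <- sort(unique(assignment$bin))
  prof <- t(vapply(bins, function(b) {
    colMeans(zmat[assignment$gene[assignment$bin == b], , drop = FALSE])
  }, numeric(ncol(zmat))))
  rownames(prof) <- bins
  prof
}
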