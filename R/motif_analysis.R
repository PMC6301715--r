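# PWM log-odds scoring and motif statistics. A PWM is a list with id,
# name, prob (4 x L base-probability matrix, rows A/C/G/T), background
# (length-4, sums to 1) and the pseudocount used for regularization.

BASES <- c("A", "C", "G", "T")

#' Build a PWM from a count (or probability) matrix
#'
#' Counts are regularized as (count + pseudocount * background) /
#' (column total + pseudocount), so each position's probabilities sum
#' to 1.
#'
#' @param counts 4 x L numeric matrix, rows in A, C, G, T order
#' @param id motif identifier
#' @param name optional display name
#' @param background base frequencies (default uniform)
#' @param pseudocount regularization mass (default 1)
#' @return a `pwm` list
#' @export
pwm_from_counts <- function(counts, id, name = id,
                            background = rep(0.25, 4), pseudocount = 1) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4, all(counts >= 0),
            abs(sum(background) - 1) < 1e-9)
  rownames(counts) <- BASES
  tot <- colSums(counts)
  prob <- sweep(counts + pseudocount * background, 2, tot + pseudocount,
                "/")
  structure(list(id = id, name = name, prob = prob,
                 background = stats::setNames(background, BASES),
                 pseudocount = pseudocount),
            class = "pwm")
}

#' Consensus sequence of a PWM (most probable base per position)
#' @param pwm a `pwm` object
#' @return character string
#' @export
pwm_consensus <- function(pwm) {
  paste(BASES[apply(pwm$prob, 2, which.max)], collapse = "")
}

#' Maximum attainable log-odds score of a PWM
#' @param pwm a `pwm` object
#' @return numeric, in bits
#' @export
pwm_max_score <- function(pwm) {
  sum(log2(apply(pwm$prob / pwm$background, 2, max)))
}

#' Read a JASPAR-style PWM text file
#'
#' Format: a `>id name` header followed by four lines
#' `A [ 4 19 0 ... ]` etc.
#'
#' @param path file path
#' @param background,pseudocount passed to [pwm_from_counts()]
#' @return named list of `pwm` objects
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 1) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no PWM headers in ", path)
  pwms <- lapply(heads, function(h) {
    hdr <- strsplit(sub("^>\\s*", "", lines[h]), "\\s+")[[1]]
    rows <- lines[h + 1:4]
    counts <- t(vapply(rows, function(r) {
      nums <- gsub("[][]", " ", sub("^\\s*[ACGT]", "", r))
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    }, numeric(length(strsplit(trimws(gsub(
      "[][]", " ", sub("^\\s*[ACGT]", "", rows[1]))), "\\s+")[[1]]))))
    pwm_from_counts(counts, id = hdr[1],
                    name = if (length(hdr) > 1) hdr[2] else hdr[1],
                    background = background, pseudocount = pseudocount)
  })
  stats::setNames(pwms, vapply(pwms, function(p) p$id, ""))
}

#' Write PWMs as JASPAR-style text (counts scaled to 100)
#'
#' @param pwms list of `pwm` objects
#' @param path output path
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$id, " ", p$name), con)
    counts <- round(p$prob * 100)
    for (b in BASES) {
      writeLines(paste0(b, " [ ", paste(counts[b, ], collapse = " "),
                        " ]"), con)
    }
  }
  invisible(path)
}

#' Scan a sequence with a PWM for log-odds hits
#'
#' The score of a window is sum over positions of
#' log2(p(base) / background(base)), in bits; both strands are scanned
#' (reverse-strand hits are reported at their forward-strand offset).
#' Windows containing N are skipped. The best score is reported even when
#' below the threshold.
#'
#' @param sequence character string over A/C/G/T/N
#' @param pwm a `pwm` object
#' @param threshold minimum score to report as a hit (default: report
#'   none below `0.8 * pwm_max_score(pwm)`)
#' @param both_strands scan the reverse strand too? Default TRUE.
#' @return list with `hits` (data.frame offset, strand, score; offsets
#'   0-based) and `best_score` (NA and `flagged = TRUE` when the sequence
#'   is shorter than the motif)
#' @export
pwm_log_odds_scan <- function(sequence, pwm,
                              threshold = 0.8 * pwm_max_score(pwm),
                              both_strands = TRUE) {
  w <- ncol(pwm$prob)
  base_idx <- match(strsplit(toupper(sequence), "")[[1]], BASES)
  n <- length(base_idx)
  empty <- data.frame(offset = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (n < w) {
    return(list(hits = empty, best_score = NA_real_, flagged = TRUE))
  }
  lo <- log2(pwm$prob / pwm$background)  # 4 x w
  score_with <- function(mat) {
    s <- numeric(n - w + 1)
    for (k in seq_len(w)) {
      s <- s + mat[, k][base_idx[k:(n - w + k)]]
    }
    s
  }
  fwd <- score_with(lo)
  strands <- rep("+", length(fwd))
  scores <- fwd
  offsets <- seq_along(fwd) - 1L
  if (both_strands) {
    # reverse-complement PWM scores the reverse strand at the same
    # forward offset
    rev_lo <- lo[4:1, w:1, drop = FALSE]
    rownames(rev_lo) <- BASES
    rev <- score_with(rev_lo)
    scores <- c(scores, rev)
    strands <- c(strands, rep("-", length(rev)))
    offsets <- c(offsets, seq_along(rev) - 1L)
  }
  ok <- !is.na(scores)
  best <- if (any(ok)) max(scores[ok]) else NA_real_
  hit <- ok & scores >= threshold
  hits <- data.frame(offset = offsets[hit], strand = strands[hit],
                     score = scores[hit], stringsAsFactors = FALSE)
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits, best_score = best, flagged = !any(ok))
}

#' Best log-odds score per sequence for each PWM
#'
#' @param sequences named character vector
#' @param pwms list of `pwm` objects
#' @return matrix sequences x motifs of best scores
#' @export
pwm_best_scores <- function(sequences, pwms) {
  out <- vapply(pwms, function(p) {
    vapply(sequences, function(s) {
      pwm_log_odds_scan(s, p, threshold = Inf)$best_score
    }, numeric(1))
  }, numeric(length(sequences)))
  out <- matrix(out, nrow = length(sequences),
                dimnames = list(names(sequences),
                                vapply(pwms, function(p) p$id, "")))
  out
}

#' Motif enrichment of target versus background sequences
#'
#' For each PWM, the fraction of sequences with at least one hit at the
#' score threshold is computed in targets and background; the p-value is
#' a one-sided binomial test of the target hit count against the
#' background hit fraction.
#'
#' @param target_seqs,background_seqs named character vectors
#' @param pwms list of `pwm` objects
#' @param threshold absolute score threshold, or NULL for
#'   `0.8 * pwm_max_score` per motif
#' @return data.frame: motif, percent_target, percent_background,
#'   p_value
#' @export
motif_enrichment <- function(target_seqs, background_seqs, pwms,
                             threshold = NULL) {
  if (length(pwms) == 0) {
    return(data.frame(motif = character(), percent_target = numeric(),
                      percent_background = numeric(),
                      p_value = numeric()))
  }
  rows <- lapply(pwms, function(p) {
    thr <- threshold %||% (0.8 * pwm_max_score(p))
    has_hit <- function(seqs) {
      vapply(seqs, function(s) {
        nrow(pwm_log_odds_scan(s, p, threshold = thr)$hits) > 0
      }, logical(1))
    }
    x <- sum(has_hit(target_seqs))
    nb <- length(background_seqs)
    bg_frac <- sum(has_hit(background_seqs)) / nb
    p_bg <- min(max(bg_frac, 0.5 / (nb + 1)), 1 - 0.5 / (nb + 1))
    pv <- stats::binom.test(x, length(target_seqs), p = p_bg,
                            alternative = "greater")$p.value
    data.frame(motif = p$id, percent_target = 100 * x / length(target_seqs),
               percent_background = 100 * bg_frac, p_value = pv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-cluster motif-score comparison
#'
#' Kruskal-Wallis omnibus test across clusters; pairwise
#' Mann-Whitney-Wilcoxon tests (BH-adjusted) are run only when the
#' omnibus p is below `gate`.
#'
#' @param scores per-region best motif scores
#' @param labels cluster label per region
#' @param gate omnibus p-value gate for the posthoc tests (default 0.05)
#' @return list with `kruskal_p`, `pairwise_p` (matrix or NULL), and
#'   per-cluster medians
#' @export
cluster_motif_scores <- function(scores, labels, gate = 0.05) {
  labels <- factor(labels)
  stopifnot(length(scores) == length(labels), nlevels(labels) >= 2)
  kw <- stats::kruskal.test(scores, labels)
  pw <- NULL
  if (kw$p.value < gate) {
    pw <- stats::pairwise.wilcox.test(scores, labels,
                                      p.adjust.method = "BH",
                                      exact = FALSE)$p.value
  }
  med <- tapply(scores, labels, stats::median)
  list(kruskal_p = kw$p.value, pairwise_p = pw, medians = med)
}

#' Motif activity by ridge regression
#'
#' Regresses per-region differential signal (e.g. H3K27Ac log2 fold
#' change) on binary motif occurrence; the penalized coefficient is the
#' motif's activity. Standard errors and p-values come from a seeded
#' residual bootstrap. Constant occurrence columns are flagged and get NA
#' activity.
#'
#' @param lfc numeric response per region
#' @param occurrence binary region x motif matrix
#' @param lambda ridge penalty (default 1)
#' @param n_boot residual-bootstrap replicates (default 200)
#' @param seed bootstrap seed
#' @return data.frame: motif, activity, se, p_value, flagged
#' @export
motif_activity <- function(lfc, occurrence, lambda = 1, n_boot = 200,
                           seed = 1L) {
  x <- as.matrix(occurrence)
  stopifnot(length(lfc) == nrow(x), all(x %in% c(0, 1)))
  motifs <- colnames(x) %||% paste0("motif", seq_len(ncol(x)))
  const <- apply(x, 2, function(col) length(unique(col)) == 1)
  xc <- scale(x[, !const, drop = FALSE], center = TRUE, scale = FALSE)
  yc <- lfc - mean(lfc)
  k <- ncol(xc)
  fit_ridge <- function(y) {
    solve(crossprod(xc) + lambda * diag(k), crossprod(xc, y))[, 1]
  }
  beta <- fit_ridge(yc)
  yhat <- xc %*% beta
  resid <- yc - yhat
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    fit_ridge(yhat + sample(resid, replace = TRUE))
  }, numeric(k))
  se <- apply(matrix(boots, nrow = k), 1, stats::sd)
  pv <- 2 * stats::pnorm(-abs(beta) / se)
  out <- data.frame(motif = motifs, activity = NA_real_, se = NA_real_,
                    p_value = NA_real_, flagged = const,
                    stringsAsFactors = FALSE)
  out$activity[!const] <- beta
  out$se[!const] <- se
  out$p_value[!const] <- pv
  out
}

#' Built-in demonstration PWMs
#'
#' Six liver-relevant motifs: GRE (glucocorticoid response element), CRE
#' (cAMP response element), FOXO forkhead site, E-box, a nuclear-receptor
#' half site and a TATA-like decoy. Matrices are synthetic (idealized
#' consensus with 85% dominant-base probability), intended for simulation
#' and testing.
#'
#' @param background base frequencies for log-odds (default uniform)
#' @return named list of `pwm` objects
#' @export
demo_pwms <- function(background = rep(0.25, 4)) {
  mk <- function(id, name, consensus) {
    chars <- strsplit(consensus, "")[[1]]
    counts <- vapply(chars, function(ch) {
      if (ch == "N") rep(25, 4) else ifelse(BASES == ch, 85, 5)
    }, numeric(4))
    pwm_from_counts(counts, id = id, name = name,
                    background = background, pseudocount = 1)
  }
  pwms <- list(
    mk("GRE", "GR_response_element", "AGAACANNNTGTTCT"),
    mk("CRE", "CREB_site", "TGACGTCA"),
    mk("FKH", "FOXO_forkhead", "TGTTTAC"),
    mk("EBOX", "Ebox_CACGTG", "CACGTG"),
    mk("NRHALF", "NR_half_site", "AGGTCA"),
    mk("TATA", "TATA_decoy", "TATAAA"))
  names(pwms) <- vapply(pwms, function(p) p$id, "")
  pwms
}
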