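# Shared fixtures, built in code. The tiny dataset is memoized so several
# test files can reuse it without regenerating.

.fixture_env <- new.env(parent = emptyenv())

tiny_config <- function(seed = 2L, ...) {
  simulation_config(seed = seed, n_genes = 300L, n_dhs = 300L,
                    genome_length = 6e6, ...)
}

tiny_dataset <- function() {
  if (is.null(.fixture_env$tiny)) {
    .fixture_env$tiny <- simulate_dataset(tiny_config())
  }
  .fixture_env$tiny
}

# brute-force oracles ------------------------------------------------------

brute_overlap <- function(a, b, min_bp = 1) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= min_bp) {
        out[[length(out) + 1]] <- data.frame(query = i, subject = j,
                                             overlap_bp = ov)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(query = integer(), subject = integer(),
                      overlap_bp = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$query, res$subject), , drop = FALSE]
}

brute_nearest <- function(centers, tss_pos) {
  vapply(centers, function(ctr) {
    d <- ctr - tss_pos
    # tie toward the smaller TSS coordinate
    best <- which(abs(d) == min(abs(d)))
    d[best[which.min(tss_pos[best])]]
  }, numeric(1))
}

brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, p[ord[i]] * m / i)
    adj[ord[i]] <- min(running, 1)
  }
  adj
}

brute_scan <- function(sequence, pwm) {
  # naive per-window rescoring on both strands
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(sequence, "")[[1]]
  w <- ncol(pwm$prob)
  res <- list()
  score1 <- function(win) {
    sum(vapply(seq_along(win), function(k) {
      log2(pwm$prob[win[k], k] / pwm$background[[win[k]]])
    }, numeric(1)))
  }
  for (off in 0:(length(chars) - w)) {
    win <- chars[(off + 1):(off + w)]
    if (any(!win %in% names(comp))) next
    fwd <- score1(win)
    rev_s <- score1(rev(unname(comp[win])))
    res[[length(res) + 1]] <- data.frame(
      offset = off, fwd = fwd, rev = rev_s)
  }
  do.call(rbind, res)
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e4) {
  start <- sample.int(max_pos, n, replace = TRUE)
  genomic_intervals(chrom = sample(chroms, n, replace = TRUE),
                    start = start,
                    end = start + sample.int(500, n, replace = TRUE),
                    name = paste0("iv", seq_len(n)))
}

nb_fixture <- function(n, lfc, mu = 200, disp = 0.05, n_rep = 3,
                       seed = 1) {
  set.seed(seed)
  counts <- cbind(
    vapply(seq_len(n_rep), function(i) {
      stats::rnbinom(n, mu = mu, size = 1 / disp)
    }, numeric(n)),
    vapply(seq_len(n_rep), function(i) {
      stats::rnbinom(n, mu = mu * 2^lfc, size = 1 / disp)
    }, numeric(n)))
  colnames(counts) <- c(paste0("A_rep", seq_len(n_rep)),
                        paste0("B_rep", seq_len(n_rep)))
  rownames(counts) <- paste0("g", seq_len(n))
  counts
}
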