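# Synthetic liver dataset generator. Every generator derives its own seed
# substream from the master seed, so an identical config yields
# byte-identical outputs and stages can be regenerated independently.

CONDITIONS_FEEDING <- c("ZT10", "ZT14_fed", "ZT14_unfed")
CONDITIONS_HORMONE <- c("fed_veh", "fed_dex", "fed_S961", "fed_combo",
                        "unfed_veh")
TF_FACTORS <- c("GR", "FOXO1", "CREB")

#' Ground-truth labels for a simulated dataset
#'
#' Draws the latent structure the pipeline must recover: per-gene class
#' (clock_driven / feeding_driven / mixed / null), feeding and clock effect
#' signs, circadian peak phase, hormone-response cluster for
#' feeding-repressed genes, and per-DHS enhancer class with gene links.
#'
#' Sign conventions: `feeding_sign = +1` means induced by feeding
#' (ZT14-fed above ZT14-unfed); `clock_sign = +1` means higher at ZT10
#' than at either ZT14 arm. Hormone clusters are assigned to genes
#' suppressed by feeding (feeding_sign = -1): cluster 2 de-repressed by
#' dex, 3 by S961, 4 by either alone, 5 only by the combination, 1 by
#' neither.
#'
#' @param config a [simulation_config()]
#' @return list with data.frames `genes` and `enhancers`
#' @export
generate_truth <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "truth"))
  n <- config$n_genes
  cls_counts <- allocate_counts(n, config$class_proportions)
  gene_class <- sample(rep(names(cls_counts), cls_counts))
  feeding_sign <- ifelse(gene_class %in% c("feeding_driven", "mixed"),
                         sample(c(-1, 1), n, replace = TRUE), 0)
  clock_sign <- ifelse(gene_class %in% c("clock_driven", "mixed"),
                       sample(c(-1, 1), n, replace = TRUE), 0)
  phase <- ifelse(gene_class == "null", NA_real_, stats::runif(n, 0, 24))
  genes <- data.frame(
    gene = sprintf("gene%04d", seq_len(n)), class = gene_class,
    feeding_sign = feeding_sign, clock_sign = clock_sign, phase = phase,
    stringsAsFactors = FALSE)

  repressed <- which(genes$feeding_sign == -1)
  genes$hormone_cluster <- NA_integer_
  if (length(repressed) > 0) {
    hc <- allocate_counts(length(repressed),
                          config$hormone_cluster_proportions)
    genes$hormone_cluster[repressed] <- sample(rep(1:5, hc))
  }

  m <- config$n_dhs
  enh_counts <- allocate_counts(m, config$enhancer_class_proportions)
  enh_class <- sample(rep(names(enh_counts), enh_counts))
  eligible <- genes$gene[genes$class %in% c("feeding_driven", "mixed")]
  linked_idx <- which(enh_class %in% c("feeding_up", "feeding_down"))
  link <- rep(NA_character_, m)
  if (length(linked_idx) > 0) {
    if (length(eligible) == 0) {
      stop("feeding-responsive DHSs require >= 1 feeding_driven or ",
           "mixed gene")
    }
    link[linked_idx] <- rep_len(sample(eligible), length(linked_idx))
  }
  enhancers <- data.frame(
    dhs = sprintf("dhs%05d", seq_len(m)), class = enh_class,
    linked_gene = link, stringsAsFactors = FALSE)
  list(genes = genes, enhancers = enhancers)
}

#' Simulated gene annotation
#'
#' Places non-overlapping genes on a single chromosome: the genome is
#' split into one slot per gene and each gene is drawn uniformly inside
#' its slot with a random strand. The TSS is the start on the plus strand
#' and end - 1 on the minus strand.
#'
#' @param config a [simulation_config()]
#' @return list with `genes` (`genomic_intervals`) and `tss` (data.frame)
#' @export
generate_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, "annotation"))
  n <- config$n_genes
  slot <- config$genome_length / n
  len <- sample(2000:8000, n, replace = TRUE)
  start <- as.integer(floor((seq_len(n) - 1) * slot +
                              stats::runif(n) * (slot - len - 1)))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  genes <- genomic_intervals(chrom = "chr1", start = start,
                             end = start + len,
                             name = sprintf("gene%04d", seq_len(n)),
                             strand = strand, sort = FALSE)
  list(genes = genes, tss = tss_from_genes(genes))
}

# Per-condition expected counts for the three feeding conditions.
.feeding_means <- function(config, truth, baseline) {
  g <- truth$genes
  d <- config$effect_size_log2fc
  mu10 <- baseline * 2^(g$clock_sign * d)
  mu_unfed <- baseline
  mu_fed <- baseline * 2^(g$feeding_sign * d)
  cbind(ZT10 = mu10, ZT14_fed = mu_fed, ZT14_unfed = mu_unfed)
}

.nb_matrix <- function(mu_by_cond, n_rep, dispersion, ids) {
  conds <- colnames(mu_by_cond)
  cols <- lapply(conds, function(cn) {
    vapply(seq_len(n_rep), function(r) {
      stats::rnbinom(nrow(mu_by_cond), mu = mu_by_cond[, cn],
                     size = 1 / dispersion)
    }, numeric(nrow(mu_by_cond)))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- unlist(lapply(conds, function(cn) {
    paste0(cn, "_rep", seq_len(n_rep))
  }))
  rownames(m) <- ids
  storage.mode(m) <- "integer"
  m
}

#' Simulated expression counts across feeding conditions
#'
#' Negative-binomial replicate counts for ZT10, ZT14-fed and ZT14-unfed
#' with class-dependent means: clock-driven genes differ at ZT10 versus
#' both ZT14 arms, feeding-driven genes differ only at ZT14-fed, mixed
#' genes show both effects and null genes are flat. Baseline means are
#' lognormal around `baseline_mean`.
#'
#' @param config a [simulation_config()]
#' @param truth output of [generate_truth()] from the same config
#' @return list with `counts` (matrix), `baseline` and `means`
#' @export
generate_expression_counts <- function(config, truth) {
  set.seed(stage_seed(config$seed, "expression"))
  baseline <- rlnorm_mean(config$n_genes, config$baseline_mean, 0.5)
  mu <- .feeding_means(config, truth, baseline)
  counts <- .nb_matrix(mu, config$n_replicates, config$dispersion,
                       truth$genes$gene)
  list(counts = counts, baseline = baseline, means = mu)
}

#' Simulated circadian reference series
#'
#' Cosine profiles with gene-specific phase sampled every 2 h over 24 h
#' plus lognormal noise (CV ~0.2). Null genes are arrhythmic (zero
#' amplitude); non-null genes have relative amplitude 0.5.
#'
#' @param config a [simulation_config()]
#' @param truth output of [generate_truth()]
#' @return list with `series` (genes x 12 matrix) and `timepoints`
#' @export
generate_circadian_series <- function(config, truth) {
  set.seed(stage_seed(config$seed, "circadian"))
  tp <- seq(0, 22, by = 2)
  g <- truth$genes
  base <- rlnorm_mean(nrow(g), config$baseline_mean, 0.5)
  amp <- ifelse(g$class == "null", 0, 0.5)
  phase <- ifelse(is.na(g$phase), 0, g$phase)
  sdlog <- sqrt(log(1 + 0.2^2))
  series <- vapply(tp, function(t) {
    mu <- base * (1 + amp * cos(2 * pi * (t - phase) / 24))
    mu * stats::rlnorm(nrow(g), -sdlog^2 / 2, sdlog)
  }, numeric(nrow(g)))
  colnames(series) <- paste0("ZT", tp)
  rownames(series) <- g$gene
  list(series = series, timepoints = tp)
}

#' Simulated enhancer landscape
#'
#' Places DHSs (400 bp) on the genome and draws H3K27Ac counts for ZT10 /
#' ZT14-fed / ZT14-unfed plus DNase counts for ZT14-fed / ZT14-unfed.
#' Feeding-responsive DHSs are placed within `coupling_distance` of their
#' linked gene's TSS (several DHSs linked to one gene occupy disjoint
#' sub-slots of the window); clock and stable DHSs occupy disjoint slots
#' of a genome-wide grid. The planted H3K27Ac and DNase log2 fold changes
#' (fed over unfed) of feeding-responsive DHSs are correlated at
#' `ac_dnase_coupling`; stable and clock DHSs get small independent
#' wiggle.
#'
#' @param config a [simulation_config()]
#' @param truth output of [generate_truth()]
#' @param annotation output of [generate_annotation()]
#' @return list with `dhs` (`genomic_intervals` + class/link columns),
#'   `ac_counts`, `dnase_counts`, and `truth_lfc` (planted log2 FCs)
#' @export
generate_enhancer_landscape <- function(config, truth, annotation) {
  set.seed(stage_seed(config$seed, "enhancers"))
  enh <- truth$enhancers
  m <- nrow(enh)
  width <- 400L
  d <- config$effect_size_log2fc

  # --- placement ---
  center <- integer(m)
  linked <- which(!is.na(enh$linked_gene))
  if (length(linked) > 0) {
    tss_pos <- stats::setNames(annotation$tss$pos, annotation$tss$gene)
    D <- config$coupling_distance
    for (gene in unique(enh$linked_gene[linked])) {
      idx <- linked[enh$linked_gene[linked] == gene]
      k <- length(idx)
      lo <- tss_pos[[gene]] - D + width / 2
      hi <- tss_pos[[gene]] + D - width / 2
      slot <- (hi - lo) / k
      center[idx] <- as.integer(floor(
        lo + (seq_len(k) - 1) * slot + stats::runif(k, 0.1, 0.9) * slot))
    }
  }
  free <- which(is.na(enh$linked_gene))
  if (length(free) > 0) {
    slot <- config$genome_length / length(free)
    margin <- min(width + 100, slot * 0.2)
    center[free] <- as.integer(floor(
      (seq_along(free) - 1) * slot +
        margin + stats::runif(length(free)) * (slot - 2 * margin)))
  }
  center <- pmax(center, width %/% 2L)

  # --- planted fold changes (fed over unfed) ---
  feeding <- enh$class %in% c("feeding_up", "feeding_down")
  sign <- ifelse(enh$class == "feeding_up", 1,
                 ifelse(enh$class == "feeding_down", -1, 0))
  ac_lfc <- ifelse(feeding, sign * d + stats::rnorm(m, 0, 0.3),
                   stats::rnorm(m, 0, 0.1))
  dnase_lfc <- stats::rnorm(m, 0, 0.1)
  if (any(feeding)) {
    rho <- config$ac_dnase_coupling
    s_ac <- stats::sd(ac_lfc[feeding])
    dnase_lfc[feeding] <- rho * ac_lfc[feeding] +
      sqrt(1 - rho^2) * s_ac * stats::rnorm(sum(feeding))
  }
  clock_sign <- ifelse(enh$class == "clock",
                       sample(c(-1, 1), m, replace = TRUE), 0)

  # --- counts ---
  base_ac <- rlnorm_mean(m, config$baseline_mean, 0.5)
  base_dn <- rlnorm_mean(m, config$baseline_mean, 0.5)
  mu_ac <- cbind(ZT10 = base_ac * 2^(clock_sign * d),
                 ZT14_fed = base_ac * 2^ac_lfc,
                 ZT14_unfed = base_ac)
  mu_dn <- cbind(ZT14_fed = base_dn * 2^dnase_lfc, ZT14_unfed = base_dn)

  ord <- order(center)
  enh_sorted <- enh[ord, , drop = FALSE]
  dhs <- genomic_intervals(
    chrom = "chr1", start = center[ord] - width %/% 2L,
    end = center[ord] + width %/% 2L, name = enh_sorted$dhs,
    strand = ".", sort = FALSE)
  dhs$class <- enh_sorted$class
  dhs$linked_gene <- enh_sorted$linked_gene

  ac_counts <- .nb_matrix(mu_ac[ord, , drop = FALSE], config$n_replicates,
                          config$dispersion, enh_sorted$dhs)
  dnase_counts <- .nb_matrix(mu_dn[ord, , drop = FALSE],
                             config$n_replicates, config$dispersion,
                             enh_sorted$dhs)
  truth_lfc <- data.frame(dhs = enh_sorted$dhs, class = enh_sorted$class,
                          ac_lfc = ac_lfc[ord], dnase_lfc = dnase_lfc[ord],
                          stringsAsFactors = FALSE)
  list(dhs = dhs, ac_counts = ac_counts, dnase_counts = dnase_counts,
       truth_lfc = truth_lfc)
}

#' Simulated transcription-factor peaks and tag densities
#'
#' Each factor (GR, FOXO1, CREB) gets a per-DHS tag density whose log is
#' shifted by `tf_separation` standard deviations at feeding-down DHSs
#' relative to all others. Called peaks (200 bp at DHS centers) cover
#' `tf_binding_rate` of DHSs, sampled with probability proportional to
#' tag density; FOXO1 and CREB share a `tf_overlap_fraction` of their
#' peaks with GR's DHSs.
#'
#' @param config a [simulation_config()]
#' @param landscape output of [generate_enhancer_landscape()]
#' @return list with `density` (n_dhs x 3 matrix), `peaks` (named list of
#'   `genomic_intervals`), and `bound` (logical n_dhs x 3 matrix)
#' @export
generate_tf_peaks <- function(config, landscape) {
  set.seed(stage_seed(config$seed, "tf"))
  dhs <- landscape$dhs
  m <- nrow(dhs)
  down <- dhs$class == "feeding_down"
  density <- vapply(TF_FACTORS, function(f) {
    exp(stats::rnorm(m, mean = config$tf_separation * down, sd = 1)) * 10
  }, numeric(m))
  rownames(density) <- dhs$name

  n_pk <- max(1L, round(config$tf_binding_rate * m))
  pick <- function(pool, k) {
    if (k <= 0 || length(pool) == 0) return(integer())
    k <- min(k, length(pool))
    if (length(pool) == 1) return(pool)
    sample(pool, k, prob = density[pool, 1])
  }
  gr_idx <- sort(pick(seq_len(m), n_pk))
  bound <- matrix(FALSE, m, 3, dimnames = list(dhs$name, TF_FACTORS))
  bound[gr_idx, "GR"] <- TRUE
  n_ov <- round(config$tf_overlap_fraction * n_pk)
  for (f in c("FOXO1", "CREB")) {
    idx <- sort(c(pick(gr_idx, n_ov),
                  pick(setdiff(seq_len(m), gr_idx), n_pk - n_ov)))
    bound[idx, f] <- TRUE
  }
  centers <- interval_center(dhs)
  peaks <- lapply(TF_FACTORS, function(f) {
    idx <- which(bound[, f])
    genomic_intervals(chrom = dhs$chrom[idx], start = centers[idx] - 100L,
                      end = centers[idx] + 100L,
                      name = paste0(f, "_", dhs$name[idx]),
                      score = density[idx, f], strand = ".")
  })
  names(peaks) <- TF_FACTORS
  list(density = density, peaks = peaks, bound = bound)
}

#' Simulated enhancer sequences with planted motifs
#'
#' Background bases are i.i.d. at the configured GC content; a fraction
#' `motif_planting_rate` of sequences receives the consensus of one
#' randomly chosen PWM at a random offset (forward strand), recorded in
#' the planted-hit list.
#'
#' @param config a [simulation_config()]
#' @param pwms list of PWMs (default [demo_pwms()])
#' @return list with `sequences` (named character vector), `pwms`, and
#'   `planted` (data.frame seq, motif, offset)
#' @export
generate_sequences_with_motifs <- function(config, pwms = demo_pwms()) {
  set.seed(stage_seed(config$seed, "sequences"))
  n <- config$n_dhs
  len <- config$seq_length
  gc <- config$gc_content
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(names(probs), len, replace = TRUE, prob = probs),
          collapse = "")
  }, "")
  names(seqs) <- sprintf("dhs%05d", seq_len(n))

  planted <- data.frame(seq = character(), motif = character(),
                        offset = integer(), stringsAsFactors = FALSE)
  if (config$motif_planting_rate > 0 && length(pwms) > 0) {
    plant <- which(stats::runif(n) < config$motif_planting_rate)
    if (length(plant) > 0) {
      which_motif <- sample(length(pwms), length(plant), replace = TRUE)
      offs <- integer(length(plant))
      for (j in seq_along(plant)) {
        p <- pwms[[which_motif[j]]]
        cons <- pwm_consensus(p)
        off <- sample.int(len - nchar(cons) + 1L, 1L) - 1L
        substr(seqs[plant[j]], off + 1L, off + nchar(cons)) <- cons
        offs[j] <- off
      }
      planted <- data.frame(seq = names(seqs)[plant],
                            motif = vapply(pwms[which_motif],
                                           function(p) p$id, ""),
                            offset = offs, stringsAsFactors = FALSE)
    }
  }
  list(sequences = seqs, pwms = pwms, planted = planted)
}

#' Simulated hormone-arm expression counts
#'
#' Fed mice receive vehicle, dex, S961 or dex + S961; an unfed vehicle
#' arm is included. Feeding-suppressed genes sit at their repressed fed
#' level under vehicle and are restored to the unfed level by the arms
#' matching their hormone cluster: cluster 2 by dex, 3 by S961, 4 by
#' either alone, 5 only by the combination, 1 by none.
#'
#' @param config a [simulation_config()]
#' @param truth output of [generate_truth()]
#' @return list with `counts` and `means`
#' @export
generate_hormone_counts <- function(config, truth) {
  set.seed(stage_seed(config$seed, "hormone"))
  g <- truth$genes
  n <- nrow(g)
  d <- config$effect_size_log2fc
  base <- rlnorm_mean(n, config$baseline_mean, 0.5)

  restores <- list(fed_dex = c(2, 4), fed_S961 = c(3, 4),
                   fed_combo = c(2, 3, 4, 5))
  repressed <- g$feeding_sign == -1
  induced <- g$feeding_sign == 1
  fed_base <- ifelse(repressed, base * 2^(-d),
                     ifelse(induced, base * 2^d, base))
  mu <- cbind(fed_veh = fed_base, fed_dex = fed_base,
              fed_S961 = fed_base, fed_combo = fed_base,
              unfed_veh = base)
  for (arm in names(restores)) {
    hit <- repressed & g$hormone_cluster %in% restores[[arm]]
    mu[hit, arm] <- base[hit]
  }
  counts <- .nb_matrix(mu, config$hormone_replicates, config$dispersion,
                       g$gene)
  list(counts = counts, means = mu)
}

#' Simulated lean/obese feeding counts
#'
#' Lean animals respond to feeding per the gene truth; in obese animals a
#' fraction `obese_response_loss` of feeding-responsive genes loses its
#' response (obese fed mean equals the unfed mean).
#'
#' @param config a [simulation_config()]
#' @param truth output of [generate_truth()]
#' @return list with `counts`, `means` and `lost` (gene ids whose
#'   response is lost in the obese arm)
#' @export
generate_obesity_counts <- function(config, truth) {
  set.seed(stage_seed(config$seed, "obesity"))
  g <- truth$genes
  n <- nrow(g)
  d <- config$effect_size_log2fc
  base <- rlnorm_mean(n, config$baseline_mean, 0.5)
  fed <- base * 2^(g$feeding_sign * d)
  responsive <- which(g$feeding_sign != 0)
  lost <- sort(sample(responsive,
                      round(config$obese_response_loss *
                              length(responsive))))
  obese_fed <- fed
  obese_fed[lost] <- base[lost]
  mu <- cbind(lean_fed = fed, lean_unfed = base,
              obese_fed = obese_fed, obese_unfed = base)
  counts <- .nb_matrix(mu, config$n_replicates, config$dispersion, g$gene)
  list(counts = counts, means = mu, lost = g$gene[lost])
}

#' Planted Gaussian cluster profiles
#'
#' Helper for clustering tests: cluster centers are rows of a Sylvester
#' Hadamard (+/-1) pattern matrix scaled by `separation / 2`, so two
#' centers differ by `separation` within-cluster standard deviations
#' along every coordinate where their patterns disagree; within-cluster
#' noise is unit Gaussian.
#'
#' @param n_per_cluster rows per cluster
#' @param k number of clusters
#' @param n_cond number of columns
#' @param separation per-coordinate center offset in within-cluster
#'   standard deviations
#' @param seed integer seed
#' @return list with `mat` and `labels`
#' @export
generate_cluster_profiles <- function(n_per_cluster, k, n_cond,
                                      separation, seed = 1L) {
  set.seed(seed)
  labels <- rep(seq_len(k), each = n_per_cluster)
  m <- 2^ceiling(log2(max(k, 2)))
  h <- matrix(1, 1, 1)
  while (ncol(h) < m) h <- rbind(cbind(h, h), cbind(h, -h))
  centers <- (separation / 2) *
    h[seq_len(k), rep_len(seq_len(m), n_cond), drop = FALSE]
  mat <- centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(length(labels) * n_cond), ncol = n_cond)
  rownames(mat) <- sprintf("row%05d", seq_along(labels))
  list(mat = mat, labels = labels)
}

#' Generate the full synthetic dataset
#'
#' Runs every generator off one config and returns all components.
#'
#' @param config a [simulation_config()]
#' @param hormone_arms include hormone-arm counts?
#' @param obesity_arms include lean/obese counts?
#' @return named list of all generated components
#' @export
simulate_dataset <- function(config, hormone_arms = TRUE,
                             obesity_arms = TRUE) {
  truth <- generate_truth(config)
  annotation <- generate_annotation(config)
  expression <- generate_expression_counts(config, truth)
  circadian <- generate_circadian_series(config, truth)
  landscape <- generate_enhancer_landscape(config, truth, annotation)
  tf <- generate_tf_peaks(config, landscape)
  seqs <- generate_sequences_with_motifs(config)
  out <- list(config = config, truth = truth, annotation = annotation,
              expression = expression, circadian = circadian,
              landscape = landscape, tf = tf, sequences = seqs)
  if (hormone_arms) out$hormone <- generate_hormone_counts(config, truth)
  if (obesity_arms) out$obesity <- generate_obesity_counts(config, truth)
  out
}

#' Write a simulated dataset to disk
#'
#' BED6 for intervals and peaks, TSV count matrices, FASTA sequences,
#' JASPAR-style PWM text and JSON ground truth.
#'
#' @param dataset output of [simulate_dataset()]
#' @param outdir output directory (created if missing)
#' @return invisibly, the named vector of written paths
#' @export
write_simulation <- function(dataset, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  paths <- c(genes = p("genes.bed"), dhs = p("dhs.bed"),
             expression = p("expression_counts.tsv"),
             circadian = p("circadian_series.tsv"),
             ac = p("h3k27ac_counts.tsv"), dnase = p("dnase_counts.tsv"),
             sequences = p("dhs_sequences.fa"), pwms = p("motifs.jaspar"),
             truth = p("ground_truth.json"))
  write_bed(dataset$annotation$genes, paths["genes"])
  write_bed(dataset$landscape$dhs, paths["dhs"])
  write_count_matrix(dataset$expression$counts, paths["expression"],
                     id_col = "gene")
  utils::write.table(
    data.frame(gene = rownames(dataset$circadian$series),
               round(dataset$circadian$series, 3), check.names = FALSE),
    paths["circadian"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_count_matrix(dataset$landscape$ac_counts, paths["ac"],
                     id_col = "dhs")
  write_count_matrix(dataset$landscape$dnase_counts, paths["dnase"],
                     id_col = "dhs")
  write_fasta(dataset$sequences$sequences, paths["sequences"])
  write_jaspar(dataset$sequences$pwms, paths["pwms"])
  for (f in names(dataset$tf$peaks)) {
    paths[paste0("peaks_", f)] <- p(paste0("peaks_", f, ".bed"))
    write_bed(dataset$tf$peaks[[f]], paths[paste0("peaks_", f)])
  }
  if (!is.null(dataset$hormone)) {
    paths["hormone"] <- p("hormone_counts.tsv")
    write_count_matrix(dataset$hormone$counts, paths["hormone"],
                       id_col = "gene")
  }
  if (!is.null(dataset$obesity)) {
    paths["obesity"] <- p("obesity_counts.tsv")
    write_count_matrix(dataset$obesity$counts, paths["obesity"],
                       id_col = "gene")
  }
  truth_out <- list(genes = dataset$truth$genes,
                    enhancers = dataset$truth$enhancers,
                    planted_motifs = dataset$sequences$planted)
  jsonlite::write_json(truth_out, paths["truth"], dataframe = "columns",
                       na = "null", digits = 6)
  invisible(paths)
}
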