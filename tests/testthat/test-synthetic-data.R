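test_that("config validation enforces proportions, counts and genome size", {
  expect_error(simulation_config(class_proportions = c(
    clock_driven = 0.5, feeding_driven = 0.5, mixed = 0.2, null = -0.2)),
    "non-negative")
  expect_error(simulation_config(class_proportions = c(
    clock_driven = 0.5, feeding_driven = 0.3, mixed = 0.1, null = 0.2)),
    "sum to 1")
  expect_error(simulation_config(n_genes = 5000, genome_length = 1e6),
               "10 kb")
  expect_error(simulation_config(dispersion = 0))
})

test_that("identical config and seed give identical outputs", {
  cfg <- tiny_config(seed = 9)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$expression$counts, d2$expression$counts)
  expect_identical(d1$landscape$dhs, d2$landscape$dhs)
  expect_identical(d1$sequences$sequences, d2$sequences$sequences)
  expect_identical(d1$truth, d2$truth)
  d3 <- simulate_dataset(tiny_config(seed = 10))
  expect_false(identical(d1$expression$counts, d3$expression$counts))
})

test_that("annotation places non-overlapping stranded genes with correct TSSs", {
  ann <- generate_annotation(tiny_config())
  g <- ann$genes
  expect_true(all(g$start >= 0 & g$start < g$end))
  expect_true(all(utils::head(g$end, -1) <= utils::tail(g$start, -1)))
  plus <- g$strand == "+"
  expect_equal(ann$tss$pos[plus], g$start[plus])
  expect_equal(ann$tss$pos[!plus], g$end[!plus] - 1L)
})

test_that("truth respects configured class counts and link invariants", {
  cfg <- tiny_config()
  tr <- generate_truth(cfg)
  expect_equal(unname(table(tr$genes$class)[names(cfg$class_proportions)]),
               unname(allocate_counts(cfg$n_genes, cfg$class_proportions)),
               ignore_attr = TRUE)
  enh_counts <- allocate_counts(cfg$n_dhs, cfg$enhancer_class_proportions)
  expect_equal(sum(tr$enhancers$class == "feeding_down"),
               unname(enh_counts["feeding_down"]))
  linked <- tr$enhancers[!is.na(tr$enhancers$linked_gene), ]
  link_class <- tr$genes$class[match(linked$linked_gene, tr$genes$gene)]
  expect_true(all(link_class %in% c("feeding_driven", "mixed")))
  expect_true(all(is.na(tr$genes$phase[tr$genes$class == "null"])))
  expect_true(all(!is.na(tr$genes$phase[tr$genes$class != "null"])))
})

test_that("null-gene counts match the configured NB moments", {
  cfg <- simulation_config(seed = 5, n_genes = 5000, genome_length = 5e7,
                           baseline_mean = 100, class_proportions = c(
                             clock_driven = 0, feeding_driven = 0,
                             mixed = 0, null = 1),
                           enhancer_class_proportions = c(
                             feeding_up = 0, feeding_down = 0,
                             clock = 0, stable = 1))
  tr <- generate_truth(cfg)
  ex <- generate_expression_counts(cfg, tr)
  # samples within a gene share its lognormal baseline, so the SE of the
  # pooled mean comes from the spread of per-gene means
  gene_means <- rowMeans(ex$counts)
  se <- sd(gene_means) / sqrt(length(gene_means))
  expect_lt(abs(mean(gene_means) - 100), 3 * se)
})

test_that("feeding-driven genes carry the planted fold change", {
  cfg <- simulation_config(seed = 6, n_genes = 1000, genome_length = 1e7,
                           effect_size_log2fc = 2, class_proportions = c(
                             clock_driven = 0, feeding_driven = 1,
                             mixed = 0, null = 0))
  tr <- generate_truth(cfg)
  ex <- generate_expression_counts(cfg, tr)
  m10 <- rowMeans(ex$counts[, grep("ZT10", colnames(ex$counts))])
  mfed <- rowMeans(ex$counts[, grep("ZT14_fed", colnames(ex$counts))])
  munf <- rowMeans(ex$counts[, grep("ZT14_unfed", colnames(ex$counts))])
  # sign-corrected planted effect: log2(ZT10 / ZT14-fed) = -sign * 2
  obs <- mean(-tr$genes$feeding_sign * log2(m10 / mfed))
  expect_lt(abs(obs - 2), 0.2)
  # ZT14-unfed tracks ZT10 for feeding-driven genes
  expect_lt(abs(mean(log2(m10 / munf))), 0.1)
})

test_that("enhancer placement respects the coupling distance", {
  cfg <- tiny_config(coupling_distance = 1e4)
  tr <- generate_truth(cfg)
  ann <- generate_annotation(cfg)
  ls <- generate_enhancer_landscape(cfg, tr, ann)
  linked <- !is.na(ls$dhs$linked_gene)
  tss_pos <- setNames(ann$tss$pos, ann$tss$gene)
  d <- abs(interval_center(ls$dhs)[linked] -
             tss_pos[ls$dhs$linked_gene[linked]])
  expect_true(all(d <= 1e4))
})

test_that("an all-stable landscape has uncorrelated planted fold changes", {
  cfg <- simulation_config(seed = 12, n_genes = 300, n_dhs = 2000,
                           genome_length = 2e7,
                           enhancer_class_proportions = c(
                             feeding_up = 0, feeding_down = 0,
                             clock = 0, stable = 1))
  tr <- generate_truth(cfg)
  ls <- generate_enhancer_landscape(cfg, tr, generate_annotation(cfg))
  r <- cor(ls$truth_lfc$ac_lfc, ls$truth_lfc$dnase_lfc)
  expect_lt(abs(r), 0.1)
})

test_that("planted fold-change coupling matches the configured correlation", {
  cfg <- simulation_config(seed = 13, n_genes = 2000, n_dhs = 4000,
                           genome_length = 4e7, ac_dnase_coupling = 0.8)
  tr <- generate_truth(cfg)
  ls <- generate_enhancer_landscape(cfg, tr, generate_annotation(cfg))
  fe <- ls$truth_lfc$class %in% c("feeding_up", "feeding_down")
  expect_lt(abs(cor(ls$truth_lfc$ac_lfc[fe], ls$truth_lfc$dnase_lfc[fe]) -
                  0.8), 0.05)
})

test_that("TF peak overlap fraction hits its limit cases", {
  base <- list(seed = 30, n_genes = 300, n_dhs = 300, genome_length = 6e6,
               enhancer_class_proportions = c(feeding_up = 0,
                                              feeding_down = 0, clock = 0,
                                              stable = 1))
  for (f in c(0, 1)) {
    cfg <- do.call(simulation_config,
                   c(base, list(tf_overlap_fraction = f,
                                tf_binding_rate = 0.4)))
    tr <- generate_truth(cfg)
    ls <- generate_enhancer_landscape(cfg, tr, generate_annotation(cfg))
    tf <- generate_tf_peaks(cfg, ls)
    ov <- overlap_pairs(tf$peaks$GR, tf$peaks$FOXO1)
    if (f == 0) {
      expect_equal(nrow(ov), 0)
    } else {
      expect_equal(nrow(ov), min(nrow(tf$peaks$GR), nrow(tf$peaks$FOXO1)))
    }
  }
})

test_that("zero separation leaves TF density uninformative about class", {
  cfg <- tiny_config(tf_separation = 0)
  tr <- generate_truth(cfg)
  ls <- generate_enhancer_landscape(cfg, tr, generate_annotation(cfg))
  tf <- generate_tf_peaks(cfg, ls)
  down <- ls$dhs$class == "feeding_down"
  p <- wilcox.test(tf$density[down, "GR"], tf$density[!down, "GR"],
                   exact = FALSE)$p.value
  expect_gt(p, 0.01)
})

test_that("sequence generator hits GC content and records plantings", {
  cfg <- simulation_config(seed = 14, n_genes = 300, n_dhs = 2000,
                           genome_length = 6e6, gc_content = 0.48,
                           motif_planting_rate = 0)
  sq <- generate_sequences_with_motifs(cfg)
  expect_equal(nrow(sq$planted), 0)
  gc <- mean(vapply(sq$sequences, function(s) {
    mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  }, numeric(1)))
  expect_lt(abs(gc - 0.48), 0.01)

  cfg2 <- tiny_config(motif_planting_rate = 0.5)
  sq2 <- generate_sequences_with_motifs(cfg2)
  expect_gt(nrow(sq2$planted), 0)
  # planted consensus attains the PWM's maximal score at its offset
  hit <- sq2$planted[1, ]
  pwm <- sq2$pwms[[hit$motif]]
  scan <- pwm_log_odds_scan(sq2$sequences[[hit$seq]], pwm,
                            threshold = pwm_max_score(pwm) - 1e-9)
  expect_true(hit$offset %in% scan$hits$offset)
  expect_equal(scan$best_score, pwm_max_score(pwm))
})

test_that("hormone arms restore unfed means per the cluster decision table", {
  cfg <- tiny_config()
  tr <- generate_truth(cfg)
  h <- generate_hormone_counts(cfg, tr)
  g <- tr$genes
  rep2 <- which(g$hormone_cluster == 2)
  rep5 <- which(g$hormone_cluster == 5)
  rep1 <- which(g$hormone_cluster == 1)
  # cluster 2: dex and combo restore, S961 does not
  expect_equal(h$means[rep2, "fed_dex"], h$means[rep2, "unfed_veh"])
  expect_equal(h$means[rep2, "fed_combo"], h$means[rep2, "unfed_veh"])
  expect_equal(h$means[rep2, "fed_S961"], h$means[rep2, "fed_veh"])
  # cluster 5: only the combination restores
  expect_equal(h$means[rep5, "fed_combo"], h$means[rep5, "unfed_veh"])
  expect_equal(h$means[rep5, "fed_dex"], h$means[rep5, "fed_veh"])
  # cluster 1: nothing restores
  expect_equal(h$means[rep1, "fed_combo"], h$means[rep1, "fed_veh"])
  # repression itself: fed vehicle sits 2^effect below unfed
  expect_equal(h$means[rep1, "unfed_veh"] / h$means[rep1, "fed_veh"],
               rep(2^cfg$effect_size_log2fc, length(rep1)))
})

test_that("written simulation files round-trip", {
  outdir <- withr::local_tempdir()
  ds <- tiny_dataset()
  paths <- write_simulation(ds, outdir)
  expect_true(all(file.exists(paths)))
  counts <- read_count_matrix(paths[["expression"]])
  expect_identical(counts, ds$expression$counts)
  dhs <- read_bed(paths[["dhs"]])
  expect_equal(dhs$start, ds$landscape$dhs$start)
  seqs <- read_fasta(paths[["sequences"]])
  expect_identical(seqs, ds$sequences$sequences)
  pwms <- read_jaspar(paths[["pwms"]])
  expect_equal(names(pwms), names(ds$sequences$pwms))
})
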