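test_that("co-occupancy Venn cells match brute force and sum to the regions", {
  regions <- genomic_intervals("chr1", seq(0, 9000, 1000),
                               seq(400, 9400, 1000),
                               name = paste0("r", 1:10))
  same <- list(A = regions, B = regions)
  co_same <- co_occupancy(regions, same)
  expect_equal(unname(co_same$venn["A+B"]), 10L)
  expect_equal(sum(co_same$venn), 10)

  a <- genomic_intervals("chr1", c(0, 1000), c(400, 1400))
  b <- genomic_intervals("chr1", c(5000, 6000), c(5400, 6400))
  co_dis <- co_occupancy(regions, list(A = a, B = b))
  expect_equal(unname(co_dis$venn["A+B"]), 0L)
  expect_equal(unname(co_dis$venn["A"]), 2L)
  expect_equal(unname(co_dis$venn["B"]), 2L)

  set.seed(41)
  regions_r <- random_intervals(80, chroms = "chr1", max_pos = 2e4)
  sets <- list(A = random_intervals(40, chroms = "chr1", max_pos = 2e4),
               B = random_intervals(40, chroms = "chr1", max_pos = 2e4),
               C = random_intervals(40, chroms = "chr1", max_pos = 2e4))
  co <- co_occupancy(regions_r, sets)
  occ_brute <- vapply(sets, function(ps) {
    vapply(seq_len(nrow(regions_r)), function(i) {
      any(ps$start < regions_r$end[i] & ps$end > regions_r$start[i])
    }, logical(1))
  }, logical(nrow(regions_r)))
  pattern <- apply(occ_brute, 1, function(r) {
    if (!any(r)) "none" else paste(names(sets)[r], collapse = "+")
  })
  for (cb in names(co$venn)) {
    expect_equal(unname(co$venn[cb]), sum(pattern == cb))
  }
  expect_equal(sum(co$venn), nrow(regions_r))
})

test_that("AUC equals the Mann-Whitney identity and hits its limits", {
  score <- c(1, 2, 3, 10, 11, 12)
  label <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  expect_equal(roc_predict(score, label)$auc, 1)

  expect_error(roc_predict(score, rep(TRUE, 6)), "non-empty")

  set.seed(43)
  for (i in 1:10) {
    n <- 200
    score <- sample(1:50, n, replace = TRUE)  # heavy ties
    label <- runif(n) < 0.4
    if (!any(label) || all(label)) next
    auc <- roc_predict(score, label)$auc
    u <- wilcox.test(score[label], score[!label],
                     exact = FALSE)$statistic
    expect_equal(auc, unname(u) / (sum(label) * sum(!label)),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(45)
  score <- c(rnorm(300), rnorm(200, 1))
  label <- rep(c(FALSE, TRUE), c(300, 200))
  ours <- roc_predict(score, label)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(label, score, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("chance-level and separated scores give the expected AUC", {
  set.seed(47)
  label <- rep(c(TRUE, FALSE), 1000)
  auc0 <- roc_predict(rnorm(2000), label)$auc
  expect_gt(auc0, 0.47)
  expect_lt(auc0, 0.53)
  auc2 <- roc_predict(rnorm(2000, mean = 2 * label), label)$auc
  expect_gte(auc2, 0.9)
})

test_that("proximity enrichment flags constructed extremes and boundaries", {
  set.seed(51)
  cfg <- simulation_config(seed = 51, n_genes = 400, genome_length = 2e7,
                           enhancer_class_proportions = c(
                             feeding_up = 0, feeding_down = 0,
                             clock = 0, stable = 1))
  genes <- generate_annotation(cfg)$genes
  tss <- tss_from_genes(genes)
  gene_set <- sample(genes$name, 50)
  sel <- tss[tss$gene %in% gene_set, ]
  at_tss <- genomic_intervals(sel$chrom, pmax(sel$pos - 100, 0),
                              sel$pos + 100)
  res <- proximity_enrichment(gene_set, list(p = at_tss), genes,
                              window = 5000, n_random = 6, seed = 2)
  expect_equal(res$observed, 1)
  expect_gt(res$relative_enrichment, 2)

  # window = 0: only peaks centered exactly at a TSS count
  g1 <- gene_set[1]
  pos1 <- tss$pos[tss$gene == g1]
  centered <- genomic_intervals("chr1", pos1 - 50, pos1 + 50)
  res0 <- proximity_enrichment(g1, list(p = centered), genes,
                               window = 0, n_random = 3, seed = 2)
  expect_equal(res0$observed, 1)
  off <- genomic_intervals("chr1", pos1 + 1, pos1 + 101)
  res_off <- proximity_enrichment(g1, list(p = off), genes,
                                  window = 0, n_random = 3, seed = 2)
  expect_equal(res_off$observed, 0)

  expect_error(proximity_enrichment(genes$name, list(p = at_tss),
                                    genes[1:10, ], random_size = 50),
               "universe")
})

test_that("random gene sets show no proximity enrichment", {
  set.seed(53)
  cfg <- simulation_config(seed = 53, n_genes = 500, genome_length = 2.5e7,
                           enhancer_class_proportions = c(
                             feeding_up = 0, feeding_down = 0,
                             clock = 0, stable = 1))
  genes <- generate_annotation(cfg)$genes
  start <- sample.int(2.5e7, 250)
  peaks <- genomic_intervals("chr1", start, start + 200)
  rel <- vapply(1:20, function(i) {
    proximity_enrichment(sample(genes$name, 60), list(p = peaks), genes,
                         window = 5000, n_random = 6,
                         seed = i)$relative_enrichment
  }, numeric(1))
  expect_gt(mean(rel), 0.8)
  expect_lt(mean(rel), 1.2)
})

test_that("dex-response bins are ordered, sized and compare covariates", {
  b <- dex_response_bins(paste0("d", 1:9), response = 9:1)
  expect_equal(as.character(b$bins$bin), rep(c("high", "medium", "low"),
                                             each = 3))
  expect_equal(b$bins$id[1:3], c("d1", "d2", "d3"))

  b10 <- dex_response_bins(paste0("d", 1:10), response = 10:1)
  expect_equal(unname(table(b10$bins$bin)), c(4, 3, 3), ignore_attr = TRUE)

  set.seed(57)
  n <- 900
  dens <- exp(rnorm(n))
  resp <- 0.8 * log(dens) + rnorm(n, sd = 0.5)
  bb <- dex_response_bins(paste0("d", 1:n), resp,
                          covariates = list(gr = dens))
  expect_lt(bb$comparisons$gr$high_vs_low_p, 0.01)
  expect_gt(bb$comparisons$gr$medians[["high"]],
            bb$comparisons$gr$medians[["low"]])

  flat <- dex_response_bins(paste0("d", 1:300), rep(1, 300),
                            covariates = list(x = rnorm(300)))
  expect_gt(flat$comparisons$x$high_vs_low_p, 0.05)
})

test_that("TF tag density at feeding-down DHSs predicts acetylation loss", {
  ds <- tiny_dataset()
  dhs <- ds$landscape$dhs
  lab <- dhs$class == "feeding_down"
  keep <- lab | dhs$class == "stable"
  for (f in c("GR", "FOXO1", "CREB")) {
    auc <- roc_predict(ds$tf$density[keep, f], lab[keep])$auc
    expect_gte(auc, 0.85)  # separation 2 sd implies AUC ~0.92
  }
})
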