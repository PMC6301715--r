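test_that("the response decision table maps flags to clusters", {
  mk <- function(ids, sig) {
    data.frame(id = ids, log2fc = ifelse(sig, 2, 0),
               fdr = ifelse(sig, 0.001, 0.9))
  }
  genes <- paste0("g", 1:6)
  # per-gene flags (dex, S961, combo)
  dex <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  s961 <- c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  combo <- c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE)
  calls <- classify_response(genes, mk(genes, dex), mk(genes, s961),
                             mk(genes, combo))
  expect_equal(calls$cluster, c(1L, 2L, 3L, 4L, 5L, 2L))

  # de-repression requires a positive fold change
  neg <- mk(genes, dex)
  neg$log2fc <- -neg$log2fc
  calls_neg <- classify_response(genes, neg, mk(genes, s961),
                                 mk(genes, combo))
  expect_false(any(calls_neg$sig_dex))

  # genes missing from a contrast are flagged unclassified
  missing <- classify_response(c(genes, "gX"), mk(genes, dex),
                               mk(genes, s961), mk(genes, combo))
  expect_true(missing$unclassified[missing$gene == "gX"])
  expect_true(is.na(missing$cluster[missing$gene == "gX"]))
})

test_that("call order and gene order do not change cluster calls", {
  set.seed(61)
  ids <- paste0("g", 1:50)
  mkr <- function() data.frame(id = sample(ids), log2fc = rnorm(50),
                               fdr = runif(50))
  d1 <- mkr(); d2 <- mkr(); d3 <- mkr()
  a <- classify_response(ids, d1, d2, d3)
  perm <- sample(50)
  b <- classify_response(ids[perm], d1[sample(50), ], d2, d3)
  expect_equal(a$cluster[match(ids, a$gene)], b$cluster[match(ids, b$gene)])
})

test_that("planted hormone clusters are recovered without dex/S961 confusion", {
  ds <- tiny_dataset()
  hc <- ds$hormone$counts
  d_f <- nb_wald_test(hc, condition_samples(hc, "unfed_veh"),
                      condition_samples(hc, "fed_veh"))
  repressed <- identify_feeding_repressed(d_f, 0.05)
  truth <- ds$truth$genes
  planted <- truth$gene[!is.na(truth$hormone_cluster)]
  expect_gte(mean(planted %in% repressed), 0.8)

  arms <- lapply(c("fed_dex", "fed_S961", "fed_combo"), function(cn) {
    nb_wald_test(hc, condition_samples(hc, "fed_veh"),
                 condition_samples(hc, cn))
  })
  calls <- classify_response(repressed, arms[[1]], arms[[2]], arms[[3]])
  tc <- truth$hormone_cluster[match(calls$gene, truth$gene)]
  ok <- !is.na(tc) & !is.na(calls$cluster)
  conf <- table(truth = tc[ok], called = calls$cluster[ok])
  for (cl in 2:5) {
    expect_gte(conf[cl, cl] / sum(conf[cl, ]), 0.7)
  }
  # no systematic dex <-> S961 confusion
  expect_lte(conf["2", "3"], 0.05 * sum(conf["2", ]))
  expect_lte(conf["3", "2"], 0.05 * sum(conf["3", ]))
})

test_that("PCA summary reproduces structure, ellipses and variance shares", {
  set.seed(67)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  # duplicated samples in two groups share ellipse centers
  dup <- cbind(m[, 1:5], m[, 1:5])
  colnames(dup) <- paste0("s", 1:10)
  ps <- pca_summary(dup, rep(c("a", "b"), each = 5))
  expect_equal(ps$ellipses$a$center, ps$ellipses$b$center)

  # variance on one axis only
  one <- rbind(seq(-2, 2, length.out = 10), matrix(0, 5, 10))
  rownames(one) <- paste0("g", 1:6)
  colnames(one) <- paste0("s", 1:10)
  ps1 <- pca_summary(one, rep("a", 10))
  expect_gt(ps1$explained[1], 0.999)

  # full-rank reconstruction from all retained components
  ps2 <- pca_summary(m, rep(c("a", "b"), each = 5))
  recon <- ps2$scores %*% t(ps2$loadings)   # samples x features
  centered <- scale(t(m), scale = FALSE)
  expect_lt(max(abs(recon - centered)), 1e-9)
  expect_true(all(diff(ps2$explained) < 1e-12))
})

test_that("combo-arm samples resemble unfed animals in PC space", {
  ds <- tiny_dataset()
  hc <- ds$hormone$counts
  d_f <- nb_wald_test(hc, condition_samples(hc, "unfed_veh"),
                      condition_samples(hc, "fed_veh"))
  repressed <- identify_feeding_repressed(d_f, 0.05)
  sf <- size_factors(hc)
  lmat <- log2(sweep(hc[repressed, , drop = FALSE], 2, sf, "/") + 1)
  ps <- pca_summary(lmat, sample_conditions(colnames(hc)))
  cen <- function(g) ps$ellipses[[g]]$center
  d_unfed <- sqrt(sum((cen("fed_combo") - cen("unfed_veh"))^2))
  d_fedveh <- sqrt(sum((cen("fed_combo") - cen("fed_veh"))^2))
  expect_lt(d_unfed, d_fedveh)
})

test_that("cluster enrichment finds a constructed signal and flags empties", {
  clusters <- data.frame(gene = paste0("g", 1:100),
                         cluster = rep(1:4, each = 25))
  universe <- clusters$gene
  reg <- clusters$gene[clusters$cluster == 2]
  res <- cluster_enrichment(clusters, reg, universe, n_random = 20,
                            seed = 3)
  expect_equal(res$cluster[which.max(res$relative_enrichment)], 2)
  expect_true(all(res$relative_enrichment[res$cluster != 2] < 1))

  with_empty <- rbind(clusters,
                      data.frame(gene = character(), cluster = integer()))
  res2 <- cluster_enrichment(
    data.frame(gene = clusters$gene,
               cluster = ifelse(clusters$cluster == 4, 1,
                                clusters$cluster)),
    reg, universe, n_random = 5, seed = 3)
  expect_false(any(res2$flagged))
})

test_that("random regulated sets give enrichment near one", {
  set.seed(71)
  clusters <- data.frame(gene = paste0("g", 1:200),
                         cluster = rep(1:5, each = 40))
  rel <- vapply(1:30, function(i) {
    reg <- sample(clusters$gene, 50)
    mean(cluster_enrichment(clusters, reg, clusters$gene, n_random = 6,
                            seed = i)$relative_enrichment)
  }, numeric(1))
  expect_gt(mean(rel), 0.9)
  expect_lt(mean(rel), 1.1)
})

test_that("obesity clustering recovers planted classes and calibrates", {
  pl <- generate_cluster_profiles(40, k = 8, n_cond = 8, separation = 3,
                                  seed = 9)
  colnames(pl$mat) <- c(paste0("lean_fed_rep", 1:2),
                        paste0("lean_unfed_rep", 1:2),
                        paste0("obese_fed_rep", 1:2),
                        paste0("obese_unfed_rep", 1:2))
  res <- obesity_cluster_analysis(pl$mat, k = 8)
  expect_gte(adjusted_rand_index(res$clusters$cluster, pl$labels), 0.8)

  expect_error(obesity_cluster_analysis(pl$mat, k = 1), ">= 2")

  # identical lean and obese generation: comparisons should rarely fire
  set.seed(73)
  m <- matrix(rnorm(200 * 8), 200, 8)
  colnames(m) <- colnames(pl$mat)
  rownames(m) <- paste0("g", 1:200)
  cal <- obesity_cluster_analysis(m, k = 4)
  ps <- unlist(cal$lean_vs_obese)
  expect_gt(median(ps), 0.1)
})
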