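# End-to-end orchestration: one YAML-style config drives simulation,
# differential testing, feeding classification, enhancer, motif,
# occupancy and hormone stages, with all randomness derived from a single
# master seed and a machine-readable JSON run report.

#' Default run configuration
#'
#' Thresholds follow the analysis conventions: gene FDR 0.01, H3K27Ac
#' FDR 0.1 (0.05 for the ROC labels), hormone FDR 0.05, 800-bp
#' quantification window, 50-kb TSS proximity window, 4 enhancer
#' clusters, 8 obesity clusters, 3 dex-response bins.
#'
#' @param seed master seed
#' @param ... overrides for nested fields (`thresholds`, `clusters`,
#'   `simulation`, `stages` lists are merged over the defaults)
#' @return a `run_config` list
#' @export
default_run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    thresholds = list(gene_fdr = 0.01, ac_fdr = 0.1, roc_fdr = 0.05,
                      hormone_fdr = 0.05, window = 800,
                      proximity_window = 5e4, rhythm_threshold = 2,
                      motif_lambda = 1),
    clusters = list(enhancer = 4, obesity = 8, dex_bins = 3),
    n_random_sets = 6,
    simulation = list(),
    stages = list(simulate = TRUE, expression = TRUE, enhancers = TRUE,
                  motifs = TRUE, occupancy = TRUE, hormone = TRUE))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; fields override [default_run_config()]
#' @return a validated `run_config`
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(default_run_config,
          c(list(seed = y$seed %||% 1L),
            y[setdiff(names(y), "seed")]))
}

validate_run_config <- function(cfg) {
  th <- cfg$thresholds
  num <- unlist(th[c("gene_fdr", "ac_fdr", "roc_fdr", "hormone_fdr",
                     "window", "proximity_window")])
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("run config thresholds must be positive numbers")
  }
  if (any(unlist(th[c("gene_fdr", "ac_fdr", "roc_fdr",
                      "hormone_fdr")]) >= 1)) {
    stop("FDR thresholds must be < 1")
  }
  if (any(unlist(cfg$clusters) < 2)) stop("cluster counts must be >= 2")
  invisible(cfg)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Simulates a dataset (unless disabled), writes every input to
#' `outdir/inputs`, reads the inputs back from disk and executes the
#' stages in dependency order: differential expression and feeding
#' classification, enhancer activity, motif analysis, TF occupancy and
#' hormone decomposition. Per-stage tables are written under `outdir`
#' and a JSON run report (stage counts, seeds, input hashes, output
#' paths) under `outdir/report.json`. Rerunning with the same config
#' yields byte-identical outputs.
#'
#' @param config a `run_config` (see [default_run_config()]) or path to
#'   a YAML config
#' @param outdir output directory
#' @return the run report, invisibly
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  report <- list(seed = config$seed, stages = list(), outputs = list())
  # the report stores paths relative to outdir so that reruns into
  # different directories stay byte-identical
  out <- function(name, df) {
    path <- .write_tsv(df, file.path(outdir, paste0(name, ".tsv")))
    report$outputs[[name]] <<- paste0(name, ".tsv")
    path
  }

  if (!isTRUE(config$stages$simulate)) {
    stop("stage 'simulate' is required in this release: the pipeline ",
         "runs on generated inputs (individual stage functions accept ",
         "external data directly)")
  }
  sim_cfg <- do.call(simulation_config,
                     c(list(seed = config$seed), config$simulation))
  ds <- simulate_dataset(sim_cfg)
  paths <- write_simulation(ds, file.path(outdir, "inputs"))
  rel <- stats::setNames(file.path("inputs", basename(paths)),
                         names(paths))
  report$stages$simulate <- list(
    n_genes = sim_cfg$n_genes, n_dhs = sim_cfg$n_dhs,
    files = as.list(rel))
  report$input_hashes <- as.list(
    stats::setNames(unname(tools::md5sum(unname(paths))), unname(rel)))

  genes <- read_bed(paths[["genes"]])
  expr <- read_count_matrix(paths[["expression"]])
  dhs <- read_bed(paths[["dhs"]])
  ac <- read_count_matrix(paths[["ac"]])
  dnase <- read_count_matrix(paths[["dnase"]])
  seqs <- read_fasta(paths[["sequences"]])
  pwms <- read_jaspar(paths[["pwms"]])
  peaks <- lapply(TF_FACTORS, function(f) {
    read_bed(paths[[paste0("peaks_", f)]])
  })
  names(peaks) <- TF_FACTORS
  tss <- tss_from_genes(genes)

  # --- expression & feeding classification ---
  sel <- NULL
  if (isTRUE(config$stages$expression)) {
    d_fed <- nb_wald_test(expr, condition_samples(expr, "ZT10"),
                          condition_samples(expr, "ZT14_fed"))
    d_unfed <- nb_wald_test(expr, condition_samples(expr, "ZT14_unfed"),
                            condition_samples(expr, "ZT10"))
    out("diff_fed_vs_zt10", d_fed)
    out("diff_zt10_vs_unfed", d_unfed)
    sel <- select_regulated(d_fed, fdr_cut = th$gene_fdr)
    stat <- stats::setNames(d_unfed$log2fc, d_unfed$id)
    qs <- rbind(
      quintile_bin(sel$induced, stat[sel$induced], "induced"),
      quintile_bin(sel$repressed, stat[sel$repressed], "repressed"))
    out("quintiles", qs)
    phases <- assign_phase(ds$circadian$series, ds$circadian$timepoints,
                           rhythm_threshold = th$rhythm_threshold)
    out("phases", phases)
    zc <- zscore_rows(ds$circadian$series)
    prof <- bin_profile(zc[qs$gene[qs$direction == "induced"], ,
                           drop = FALSE],
                        qs[qs$direction == "induced", ])
    out("bin_profiles_induced",
        data.frame(bin = rownames(prof), prof, check.names = FALSE))
    report$stages$expression <- list(
      n_induced = length(sel$induced),
      n_repressed = length(sel$repressed),
      n_rhythmic = sum(phases$rhythmic))
  }

  # --- enhancer activity ---
  ac_de <- NULL
  if (isTRUE(config$stages$enhancers)) {
    ac_de <- differential_acetylation(
      ac, condition_samples(ac, "ZT14_unfed"),
      condition_samples(ac, "ZT14_fed"), fdr_cut = th$ac_fdr)
    dn_de <- nb_wald_test(dnase, condition_samples(dnase, "ZT14_unfed"),
                          condition_samples(dnase, "ZT14_fed"))
    out("ac_differential", ac_de$result)
    out("dnase_differential", dn_de)
    de_ids <- c(ac_de$up, ac_de$down)
    r_de <- fc_correlation(dn_de$log2fc, ac_de$result$log2fc,
                           subset = ac_de$result$id %in% de_ids)
    r_all <- fc_correlation(dn_de$log2fc, ac_de$result$log2fc)
    ks_up <- tss_distance_enrichment(
      dhs[dhs$name %in% ac_de$up, ],
      dhs[!dhs$name %in% de_ids, ],
      tss[tss$gene %in% (sel$induced %||% genes$name), ])
    ks_down <- tss_distance_enrichment(
      dhs[dhs$name %in% ac_de$down, ],
      dhs[!dhs$name %in% de_ids, ],
      tss[tss$gene %in% (sel$repressed %||% genes$name), ])
    cond_means <- vapply(CONDITIONS_FEEDING, function(cn) {
      rowMeans(ac[, condition_samples(ac, cn), drop = FALSE])
    }, numeric(nrow(ac)))
    zac <- zscore_rows(log2(cond_means + 1))
    ecl <- cluster_enhancers(zac, k = config$clusters$enhancer)
    out("enhancer_clusters", ecl$clusters)
    report$stages$enhancers <- list(
      n_up = length(ac_de$up), n_down = length(ac_de$down),
      r_de = r_de$r, r_all = r_all$r,
      ks_p_up = ks_up$p_value, ks_p_down = ks_down$p_value)
    ecl_lab <- stats::setNames(ecl$clusters$cluster, ecl$clusters$id)
  }

  # --- motif analysis ---
  if (isTRUE(config$stages$motifs)) {
    if (is.null(ac_de)) stop("stage 'motifs' requires stage 'enhancers'")
    best <- pwm_best_scores(seqs, pwms)
    down_ids <- intersect(ac_de$down, names(seqs))
    set.seed(stage_seed(config$seed, "motif_background"))
    bg_pool <- setdiff(names(seqs), down_ids)
    bg_ids <- sample(bg_pool, min(2000, length(bg_pool)))
    enr <- motif_enrichment(seqs[down_ids], seqs[bg_ids], pwms)
    out("motif_enrichment", enr)
    common <- intersect(names(ecl_lab), rownames(best))
    kw <- lapply(pwms, function(p) {
      cluster_motif_scores(best[common, p$id], ecl_lab[common])
    })
    out("motif_cluster_scores",
        data.frame(motif = names(kw),
                   kruskal_p = vapply(kw, `[[`, 0, "kruskal_p")))
    occ <- 1 * (best >= rep(0.8 * vapply(pwms, pwm_max_score, 0),
                            each = nrow(best)))
    lfc <- stats::setNames(ac_de$result$log2fc, ac_de$result$id)
    keep <- intersect(rownames(occ), names(lfc)[!is.na(lfc)])
    act <- motif_activity(lfc[keep], occ[keep, , drop = FALSE],
                          lambda = th$motif_lambda,
                          seed = stage_seed(config$seed, "motif_boot"))
    out("motif_activity", act)
    report$stages$motifs <- list(
      n_motifs = length(pwms), n_target = length(down_ids),
      n_background = length(bg_ids))
  }

  # --- TF occupancy ---
  if (isTRUE(config$stages$occupancy)) {
    if (is.null(ac_de)) {
      stop("stage 'occupancy' requires stage 'enhancers'")
    }
    co <- co_occupancy(dhs, peaks)
    out("cooccupancy", co$table)
    out("cooccupancy_venn",
        data.frame(combination = names(co$venn), n = co$venn))
    roc_de <- differential_acetylation(
      ac, condition_samples(ac, "ZT14_unfed"),
      condition_samples(ac, "ZT14_fed"), fdr_cut = th$roc_fdr)
    lab <- dhs$name %in% roc_de$down
    keep <- lab | !(dhs$name %in% c(roc_de$up, roc_de$down))
    aucs <- vapply(TF_FACTORS, function(f) {
      roc_predict(co$table[[paste0("density_", f)]][keep],
                  lab[keep])$auc
    }, numeric(1))
    prox <- proximity_enrichment(
      sel$repressed %||% genes$name, peaks, genes,
      window = th$proximity_window, n_random = config$n_random_sets,
      seed = stage_seed(config$seed, "proximity"))
    out("roc_auc", data.frame(factor = TF_FACTORS, auc = aucs))
    report$stages$occupancy <- list(
      venn = as.list(co$venn), auc = as.list(aucs),
      proximity_observed = prox$observed,
      proximity_relative = prox$relative_enrichment,
      proximity_perm_p = prox$perm_p)
  }

  # --- hormone decomposition ---
  if (isTRUE(config$stages$hormone)) {
    hc <- ds$hormone$counts
    d_feed <- nb_wald_test(hc, condition_samples(hc, "unfed_veh"),
                           condition_samples(hc, "fed_veh"))
    repressed <- identify_feeding_repressed(d_feed,
                                            fdr_cut = th$hormone_fdr)
    arms <- list(dex = "fed_dex", s961 = "fed_S961", combo = "fed_combo")
    d_arm <- lapply(arms, function(cn) {
      nb_wald_test(hc, condition_samples(hc, "fed_veh"),
                   condition_samples(hc, cn))
    })
    calls <- classify_response(repressed, d_arm$dex, d_arm$s961,
                               d_arm$combo, fdr_cut = th$hormone_fdr)
    out("hormone_clusters", calls)
    sf <- size_factors(hc)
    lmat <- log2(sweep(hc[repressed, , drop = FALSE], 2, sf, "/") + 1)
    pca <- pca_summary(lmat, sample_conditions(colnames(hc)))
    out("pca_scores",
        data.frame(sample = rownames(pca$scores),
                   group = sample_conditions(rownames(pca$scores)),
                   pca$scores[, 1:2, drop = FALSE]))
    enr <- cluster_enrichment(
      calls[!calls$unclassified, ],
      regulated = calls$gene[which(calls$sig_dex)],
      universe = calls$gene[!calls$unclassified],
      n_random = config$n_random_sets,
      seed = stage_seed(config$seed, "cluster_enrichment"))
    out("hormone_cluster_enrichment", enr)
    ob <- ds$obesity$counts
    zob <- zscore_rows(log2(ob + 1))
    keep_ob <- !attr(zob, "constant")
    oba <- obesity_cluster_analysis(
      zob[keep_ob, , drop = FALSE], k = config$clusters$obesity,
      regulated_sets = list(
        dex = calls$gene[which(calls$sig_dex)],
        s961 = calls$gene[which(calls$sig_s961)]),
      n_random = config$n_random_sets,
      seed = stage_seed(config$seed, "obesity_enrichment"))
    out("obesity_clusters", oba$clusters)
    report$stages$hormone <- list(
      n_repressed = length(repressed),
      cluster_sizes = as.list(table(calls$cluster)),
      pca_explained = pca$explained[1:2])
  }

  report_path <- file.path(outdir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                       digits = 8, pretty = TRUE)
  report$outputs$report <- "report.json"
  invisible(report)
}
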