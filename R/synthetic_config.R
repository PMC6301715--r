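#' Simulation configuration for the synthetic liver dataset
#'
#' Encodes the statistical structure of the experimental design the
#' pipeline analyzes: three feeding conditions (ZT10, ZT14-fed,
#' ZT14-unfed) with negative-binomial replicate counts, gene classes
#' (clock-driven, feeding-driven, mixed, null), an enhancer landscape
#' whose H3K27Ac and DNase changes are coupled for feeding-responsive
#' DHSs, transcription-factor occupancy whose tag density separates
#' feeding-down from stable DHSs, planted motifs in enhancer sequences,
#' and glucocorticoid/insulin (dex / S961) response clusters for
#' feeding-repressed genes.
#'
#' @param seed master seed; fully determines every generated output
#' @param n_genes number of genes
#' @param n_dhs number of DNase hypersensitive sites
#' @param n_replicates replicates per feeding condition (default 3, as in
#'   the H3K27Ac and expression designs)
#' @param hormone_replicates replicates per hormone arm (default 4)
#' @param genome_length single-chromosome genome size in bases; must be at
#'   least `n_genes * 1e4`
#' @param class_proportions named fractions over gene classes
#'   clock_driven, feeding_driven, mixed, null (sum to 1)
#' @param effect_size_log2fc planted |log2 fold change| for regulated
#'   genes and enhancers (default 2)
#' @param dispersion NB dispersion alpha (variance m + alpha m^2)
#' @param baseline_mean expected baseline count per feature
#' @param coupling_distance maximum distance (bases) between a
#'   feeding-responsive DHS center and its linked gene's TSS
#' @param motif_planting_rate fraction of enhancer sequences receiving a
#'   planted motif consensus
#' @param hormone_cluster_proportions named fractions over response
#'   clusters cluster1..cluster5 (sum to 1)
#' @param enhancer_class_proportions named fractions over DHS classes
#'   feeding_up, feeding_down, clock, stable (sum to 1)
#' @param ac_dnase_coupling planted Pearson correlation between H3K27Ac
#'   and DNase log2 fold changes at feeding-responsive DHSs
#' @param gc_content background GC fraction of enhancer sequences
#'   (default 0.48, the empirical GC of randomly sampled liver DHSs)
#' @param seq_length enhancer sequence length in bases
#' @param tf_overlap_fraction fraction of secondary-factor peaks that
#'   co-occur with the primary factor (default 0.6)
#' @param tf_separation shift, in log-scale standard deviations, of TF tag
#'   density at feeding-down DHSs relative to stable DHSs (default 2)
#' @param tf_binding_rate fraction of DHSs carrying a called peak per
#'   factor
#' @param obese_response_loss fraction of feeding-regulated genes whose
#'   feeding response is lost in the obese arm
#' @return a validated `sim_config` list
#' @export
simulation_config <- function(
    seed = 1L,
    n_genes = 2000L,
    n_dhs = 2000L,
    n_replicates = 3L,
    hormone_replicates = 4L,
    genome_length = 4e7,
    class_proportions = c(clock_driven = 0.25, feeding_driven = 0.25,
                          mixed = 0.05, null = 0.45),
    effect_size_log2fc = 2,
    dispersion = 0.05,
    baseline_mean = 200,
    coupling_distance = 2e4,
    motif_planting_rate = 0.3,
    hormone_cluster_proportions = c(cluster1 = 0.4, cluster2 = 0.15,
                                    cluster3 = 0.15, cluster4 = 0.15,
                                    cluster5 = 0.15),
    enhancer_class_proportions = c(feeding_up = 0.04, feeding_down = 0.04,
                                   clock = 0.12, stable = 0.80),
    ac_dnase_coupling = 0.8,
    gc_content = 0.48,
    seq_length = 400L,
    tf_overlap_fraction = 0.6,
    tf_separation = 2,
    tf_binding_rate = 0.5,
    obese_response_loss = 0.5) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_dhs = as.integer(n_dhs),
              n_replicates = as.integer(n_replicates),
              hormone_replicates = as.integer(hormone_replicates),
              genome_length = genome_length,
              class_proportions = class_proportions,
              effect_size_log2fc = effect_size_log2fc,
              dispersion = dispersion, baseline_mean = baseline_mean,
              coupling_distance = coupling_distance,
              motif_planting_rate = motif_planting_rate,
              hormone_cluster_proportions = hormone_cluster_proportions,
              enhancer_class_proportions = enhancer_class_proportions,
              ac_dnase_coupling = ac_dnase_coupling,
              gc_content = gc_content, seq_length = as.integer(seq_length),
              tf_overlap_fraction = tf_overlap_fraction,
              tf_separation = tf_separation,
              tf_binding_rate = tf_binding_rate,
              obese_response_loss = obese_response_loss)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  check_frac <- function(p, what, names_needed) {
    if (!setequal(names(p), names_needed)) {
      stop(what, " must have entries ", paste(names_needed, collapse = ", "))
    }
    if (abs(sum(p) - 1) > 1e-9) stop(what, " must sum to 1")
    if (any(p < 0)) stop(what, " must be non-negative")
  }
  check_frac(cfg$class_proportions, "class_proportions",
             c("clock_driven", "feeding_driven", "mixed", "null"))
  check_frac(cfg$hormone_cluster_proportions, "hormone_cluster_proportions",
             paste0("cluster", 1:5))
  check_frac(cfg$enhancer_class_proportions, "enhancer_class_proportions",
             c("feeding_up", "feeding_down", "clock", "stable"))
  stopifnot(cfg$n_genes > 0, cfg$n_dhs > 0, cfg$n_replicates > 0,
            cfg$hormone_replicates > 0, cfg$dispersion > 0,
            cfg$baseline_mean > 0, cfg$seq_length > 0,
            cfg$gc_content > 0, cfg$gc_content < 1,
            cfg$motif_planting_rate >= 0, cfg$motif_planting_rate <= 1,
            cfg$tf_overlap_fraction >= 0, cfg$tf_overlap_fraction <= 1,
            cfg$tf_binding_rate > 0, cfg$tf_binding_rate <= 1,
            abs(cfg$ac_dnase_coupling) <= 1)
  if (cfg$genome_length < cfg$n_genes * 1e4) {
    stop("genome_length must be >= n_genes * 10 kb (",
         format(cfg$n_genes * 1e4, scientific = FALSE),
         " bases for n_genes = ", cfg$n_genes, ")")
  }
  invisible(cfg)
}
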