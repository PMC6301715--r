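# prandialreg

Feeding, not just the circadian clock, drives a large share of the
diurnal liver transcriptome: many genes that change between ZT10 (late
light phase) and ZT14 (after dark-onset feeding) fail to change when
food is withheld, and the enhancers behind them lose or gain H3K27
acetylation with feeding. `prandialreg` is an R implementation of the
integrative analysis that separates these feeding-driven from
clock-driven components across gene expression, enhancer activity,
transcription-factor occupancy and hormone response — packaged for
statisticians and genomicists who want each stage as a tested, reusable
function rather than a one-off script collection.

## What it computes

* **Differential testing** (`nb_wald_test`) — a two-group
  negative-binomial Wald test with median-of-ratios normalization,
  method-of-moments dispersion shrunk 50/50 toward a log-linear
  mean-dispersion trend, and a moderated-t reference
  (df = residual + 8). Variance model: `Var = m + alpha * m^2`.
* **Feeding classification** (`select_regulated`, `quintile_bin`,
  `assign_phase`) — genes regulated between ZT10 and ZT14-fed
  (FDR < 0.01) are binned into quintiles by
  |log2FC(ZT10 vs ZT14-unfed)|, the change that *persists without
  food*: Q1 = feeding-independent (clock-driven), Q5 =
  feeding-dependent. Circadian phase comes from a least-squares cosinor
  fit, `y = m + a*cos(2*pi*(t - phi)/24)`.
* **Enhancer activity** (`quantify_at_dhs`,
  `differential_acetylation`, `fc_correlation`,
  `tss_distance_enrichment`, `cluster_enhancers`) — H3K27Ac quantified
  in an 800-bp window centered on each DNase hypersensitive site (DHS),
  differential acetylation at FDR < 0.1, Pearson correlation of DNase
  vs H3K27Ac log2 fold changes (r_de on differential DHSs vs r_all on
  all), Kolmogorov-Smirnov TSS-distance enrichment, and Ward
  clustering of condition z-profiles.
* **Motif analysis** (`pwm_log_odds_scan`, `motif_enrichment`,
  `cluster_motif_scores`, `motif_activity`) — PWM log-odds scanning of
  both strands (`score = sum log2(p_base / bg_base)`), enrichment
  against sampled background DHSs, Kruskal-Wallis + gated pairwise
  Mann-Whitney comparisons across enhancer clusters, and motif
  activity as a ridge regression of per-DHS acetylation change on
  motif occurrence with bootstrap errors.
* **TF occupancy** (`co_occupancy`, `roc_predict`,
  `proximity_enrichment`, `dex_response_bins`) — GR/FOXO1/CREB
  co-occupancy Venn counts, ROC prediction of feeding-reduced
  acetylation from tag density (AUC via the Mann-Whitney identity
  `AUC = U/(n1*n0)`), and resampling-null enrichment of peaks within
  50 kb of a gene set's TSSs relative to seeded random gene sets.
* **Hormone decomposition** (`identify_feeding_repressed`,
  `classify_response`, `pca_summary`, `cluster_enrichment`,
  `obesity_cluster_analysis`) — feeding-repressed genes (FDR < 0.05)
  classified into five dexamethasone / S961 response clusters by a
  fixed decision table, PCA with 0.9 error ellipses, and per-cluster
  resampling enrichments, including an eight-cluster lean/obese
  analysis.
* **Synthetic data** (`simulation_config`, `simulate_dataset`) — a
  seeded generator that reproduces the statistical structure of the
  experimental designs (NB replicate counts over ZT10 / ZT14-fed /
  ZT14-unfed, coupled enhancer landscapes, shifted TF tag densities,
  planted motifs, hormone arms), with ground-truth labels for
  parameter-recovery testing.

## Worked example

```r
library(prandialreg)

cfg <- default_run_config(
  seed = 1,
  simulation = list(n_genes = 500, n_dhs = 500, genome_length = 1e7))
report <- run_pipeline(cfg, "demo_out")

str(report$stages$expression)
#> $ n_induced  : int 129
#> $ n_repressed: int 133
#> $ n_rhythmic : int 223
str(report$stages$enhancers)
#> $ n_up     : int 27
#> $ n_down   : int 24
#> $ r_de     : num 0.772
#> $ r_all    : num 0.625
```

129 genes come up and 133 go down between ZT10 and ZT14-fed at
FDR < 0.01; 27 DHSs gain and 24 lose H3K27Ac with feeding at FDR < 0.1;
and DNase accessibility changes track acetylation changes much more
tightly at the differential DHSs (r_de = 0.77) than genome-wide
(r_all = 0.63) — the qualitative signature of feeding-controlled
enhancer activation. Per-stage tables (quintiles, phases, differential
results, clusters, ROC, enrichments) are written under `demo_out/`,
with a machine-readable run report in `demo_out/report.json`. Rerunning
with the same config and seed reproduces every file byte-for-byte.

A thin CLI wrapper ships in `inst/cli/prandialreg.R`:

```sh
Rscript inst/cli/prandialreg.R simulate --outdir sim_out --seed 7
Rscript inst/cli/prandialreg.R run --outdir run_out --seed 7
```

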