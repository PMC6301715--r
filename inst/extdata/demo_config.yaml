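# Desk-scale demo configuration for run_pipeline / the CLI wrapper.
seed: 1
thresholds:
  gene_fdr: 0.01
  ac_fdr: 0.1
  hormone_fdr: 0.05
simulation:
  n_genes: 500
  n_dhs: 500
  genome_length: 10000000
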