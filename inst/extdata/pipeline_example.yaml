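# Example pipeline configuration (small synthetic run)
simulation:
  n_genes: 1000
  n_celltypes: 6
  signatures_per_celltype: 40
  phenotype_effect: 0.7
  noise_sd: 0.5
n_draws: 2000
seed: 42
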