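# Demo configuration for run_derivation_pipeline() / run_calcium_pipeline();
# load with read_pipeline_config(). Small enough to complete in minutes on
# one CPU while recovering the planted signal.
seed: 7
sc:
  cells_per_group: 150
  n_genes: 800
  effect_size: 3
ca_sim:
  n_cells: 20
  share_prob: 0.9
  noise_sd: 0.05
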