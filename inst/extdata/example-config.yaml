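# Example spacederm pipeline configuration: simulate a multi-mission study and
# run every stage. See ?validate_config for all keys and defaults.
simulation:
  preset: multi-mission
  n_genes: 2000
params:
  fdr_threshold: 0.1
  min_missions: 2
  n_perm: 1000
  min_cluster_size: 20
seed: 1
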