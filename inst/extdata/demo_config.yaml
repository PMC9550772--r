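seed: 1
out_dir: monoallelix_run
populations:
- popA
- popB
simulate:
  n_genes: 600
  class_proportions:
    biallelic: 0.72
    DeMA_mat: 0.055
    DeMA_pat: 0.01
    RaMA: 0.015
    not_expressed: 0.2
  mean_expression:
    log_mean: 4.6051702
    log_sd: 1.0
  nb_dispersion: 0.1
  n_replicates: 3
  n_cells: 80
  dropout: 0.3
  leak: 0.005
  nascent_only_frac: 0.314
  mature_only_frac: 0.605
thresholds:
  min_total: 5
  mono_fraction: 0.98
  min_cells: 5
  rama_min_cells: 3
  max_biallelic_frac: 0.1
  min_expressed_frac: 0.05
transcript:
  min_detect: 1
compare:
  n_boot: 2000
enrich:
  n_terms: 12
  term_size: 25
  n_background_draws: 500
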