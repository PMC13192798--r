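# Leakage sweep over cross-feeding ensembles (reduced scale for a quick
# demonstration; the study scale uses n_communities: 10, n_sample: 200 and
# the full leakage grid). Run: crmge sweep --config sweep_crossfeeding.yaml
seed: 101
ensemble:
  n_species: 15
  n_producers: 5
  mu_center: 1.0
  mu_spread: 0.3
  beta_range: [0.05, 0.95]
  Y_fixed: 0.5
  C0: 10.0
  x0: 0.01
  KM: 1.0
  leakage_grid: [0.1, 0.4, 0.8]
  n_communities: 3
  background_mode: subsample
  n_sample: 60
  n_bins: 20
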