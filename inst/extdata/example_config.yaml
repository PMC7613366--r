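# Example experiment configuration for vitispec::run_experiment().
# Omitted keys fall back to the package defaults (see ?default_config).
seed: 42
metals: [Cu, Zn, Pb, Cr, Cd]
tracks: [wavelengths, indices]
scale_before_split: false
split:
  fraction: 0.7
  stratify: true
pls:
  k_max: 10
  v_folds: 10
mlr:
  alpha_enter: 0.05
svr:
  grid: small
  v_folds: 5
synthetic:
  design:
    replicates_per_cell: 4
    leaves_per_pot: 5
  response:
    band_amp: 0.012
    band_cv: 0.3
  noise:
    smooth_sd: 0.01
    uv_sd: 0.02
    conc_cv: 0.09
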