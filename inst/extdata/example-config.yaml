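# Example cytocnv run configuration. Any field omitted falls back to
# default_run_config(); seeds make the run fully reproducible.
seed: 4
map:
  n_chrom: 1
  markers_per_band: 64
  bands_per_chrom: 10
cohort:
  n_case: 20
  n_control: 20
planting:
  effect_band: "1q3.1"
  case_rate: 0.8
  control_rate: 0.2
caller:
  n_perm: 200
  snr_threshold: 2.0
screening:
  p1: 0.01
  p2: 0.05
gmc:
  n_voxels: 800
  n_components: 4
  k: mdl
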