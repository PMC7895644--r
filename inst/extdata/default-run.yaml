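# Default pipeline run: a small simulated cohort under the 20-minute
# laboratory protocol, with typical device-log artifacts injected.
seed: 1
n_participants: 8
n_incomplete_cress: 0
n_incomplete_aspire: 0
tol: 2
simulation:
  n_puffs_per_hand: 6
  noise_sd: 0.2
  sampling_rate: 30
  watch_hand: left
  pd_distribution:
    median_ms: 1500
    sigma: 0.3
  ipi_distribution:
    median_ms: 20000
    sigma: 0.4
artifacts:
  leading_ipi_ms: 75000
  split_probability: 0.15
  split_fragment_pd_ms: 5
  split_gap_ms: 330
  jitter_sd_ms: 60
segmentation:
  onset_fraction: 0.5
  min_plateau_ms: 500
  min_return_ms: 300
cleaning:
  min_plausible_pd_ms: 300
  leading_ipi_rule: drop_if_over_ms
  leading_ipi_threshold_ms: 60000
  merge_fragments: true
outlier_rule:
  method: range
  min_ipi_ms: 1000
  max_ipi_ms: 120000
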