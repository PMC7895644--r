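# smoketop

Smoking topography — how a cigarette is actually smoked — is usually
summarised by two quantities: the **puff duration** (PD, the milliseconds a
smoker inhales in one intake) and the **interpuff interval** (IPI, the
milliseconds from the end of one puff to the beginning of the next).
Together with the puff count they determine nearly every other topography
measure (total smoking time, puffs per cigarette, puff velocity).

Two very different instruments measure them. Mouthpiece topography devices
(CReSS-style) record per-puff airflow, but interfere with natural smoking
and are prone to characteristic artifacts: physically impossible
milliseconds-long "puffs" created by splitting one inhalation across
records, and a spurious long first interval spanning device power-on to the
first puff. Wrist-worn accelerometers are unobtrusive: a puff appears as a
stereotyped hand-to-mouth gesture — from a resting wrist pose, a negligible
change in x (about ±1 m/s²), a moderate drop in y (about −4 m/s²) and a
sharp drop in z (about −8 m/s²), then a period of equilibrated values
around (9, −5, −3) m/s² while the hand holds the cigarette at the mouth,
ending when all axes return to rest.

`smoketop` is an R package for researchers comparing the two methods. It
provides:

- **a session simulator** (`simulate_session()`, `simulate_cohort()`)
  generating 20-minute laboratory sessions — 6 minutes of smoking split
  evenly between hands, packing and other confounder movements — as 30 Hz
  3-axis accelerometer traces with known ground-truth puff events, plus
  paired CReSS-style logs with configurable artifact injection
  (`simulate_cress_log()`);
- **a gesture segmenter** (`detect_puffs()`) operationalising the puff
  signature with hysteresis thresholds and linear-ramp boundary
  refinement, plus per-session resting-pose estimation
  (`estimate_resting_pose()`);
- **topography derivation** (`events_to_topography()`,
  `cress_to_topography()`, `summarize_topography()`,
  `topography_histogram()`);
- **device-log correction** (`clean_cress()`, `correct_ipis()`,
  `ccress_pipeline()`): plausibility filtering of fragment records,
  removal of the leading device-on interval, and substitution of
  abnormally short or long IPIs by the mean of the remaining ones;
- **agreement statistics** (`run_comparison()`, `pearson_r2()`,
  `puff_count_concordance()`, `paired_series_r2()`) per participant and
  pooled, with `tidy()`/`glance()` accessors and `autoplot()` methods.

## Worked example

Simulate one laboratory session, detect its puffs, and summarise:

```r
library(smoketop)

sess <- simulate_session(simulation_config(seed = 8, noise_sd = 0.2))
sess$trace
#> <accel_trace: 36000 samples at 30 Hz, 1200.0 s>

events <- detect_puffs(sess$trace)
events
#> # A tibble: 6 × 3
#>   start_ms end_ms hand
#>      <dbl>  <dbl> <chr>
#> 1   325506 326974 unknown
#> 2   345645 347576 unknown
#> 3   360514 361818 unknown
#> 4   367815 369104 unknown
#> 5   384865 386740 unknown
#> 6   401492 402958 unknown

topo <- events_to_topography(events)
topo
#> <topography [aspire]: 6 puffs, 5 IPIs; median PD 1467 ms, median IPI 14752 ms>
```

The six detected events are the six left-hand (watch-side) puffs; the six
right-hand puffs exist in `sess$truth` but leave no wrist gesture, exactly
as a watch worn on one wrist misses the other hand. The median PD of
1467 ms and median IPI of 14.8 s are this participant's session-level
topography.

Correct the paired device log and inspect what was repaired:

```r
log <- simulate_cress_log(sess$truth,
                          cress_artifact_config(seed = 9,
                                                split_probability = 0.25,
                                                jitter_sd_ms = 60))
corr <- ccress_pipeline(log)
corr$report
#> # A tibble: 8 × 3
#>   action               record_index detail
#> 1 drop_leading_ipi                1 removed 75161 ms device-on interval
#> 2 merge_into_preceding            2 merged 4 ms record (+343 ms gap) into record 1
#> ... (6 more fragment merges)

corr$series
#> <topography [cress_corrected]: 12 puffs, 11 IPIs; median PD 1513 ms, median IPI 18195 ms>
```

Cleaning restored the 12 true puffs from a 20-record artifact-laden log;
the corrected series can then be compared against the watch-side one with
`paired_series_r2()`, or across a whole cohort with `simulate_cohort()`
followed by `run_comparison()`.

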