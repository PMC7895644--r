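---
title: "Methods: gesture segmentation, device-log correction, and the session simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gesture segmentation, device-log correction, and the session simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smoketop)
```

## The measurement problem

A smoking session is characterised by its topography: the ordered puff
durations (PD) and interpuff intervals (IPI), in milliseconds. Mouthpiece
topography devices measure these from inhalation airflow per puff, but
exhibit two artifact modes that corrupt naive per-puff analysis: one
physical puff reported as several records separated by sub-second
intervals (leaving fragment records a few milliseconds long), and a long
first interval that spans device power-on to the first puff rather than
any interpuff gap. A wrist accelerometer measures the same topography
indirectly, through the hand-to-mouth gesture. `smoketop` implements both
measurement paths and the statistics to compare them, and ships a
simulator so that every stage can be validated against known ground truth.

## The gesture model

At rest the watch-side wrist sits at a participant-specific pose; while
the hand holds the cigarette at the mouth the pose settles near
(9, −5, −3) m/s². The onset of a puff is a drop of about 4 m/s² in y and
8 m/s² in z, with x essentially unchanged; the end is the return of all
axes to the resting state. Poses vary across participants, so the
segmenter estimates the resting pose per session rather than assuming one.

The simulator renders a puff as a trapezoid: a linear ramp from rest to
plateau over `transition_ms` (default 500 ms), a plateau hold, and a ramp
back. **A truth puff event spans the plateau interval only** — the hold is
the inhalation, and its length is the drawn PD; the ramps are the
transport of the hand and lie just outside the event. Intervals are
half-open `[start_ms, end_ms)` so PD = end − start and adjacency are
unambiguous.

## Segmentation

`detect_puffs()` works in three stages:

1. **Trigger.** All axes are smoothed with a centered 5-sample moving
   average (~167 ms at 30 Hz — wide enough to suppress sample noise,
   narrow relative to 500 ms ramps). A candidate opens where smoothed y
   and z both drop below rest by at least `onset_fraction` (default 0.5)
   of the nominal 4 and 8 m/s² deltas. x is ignored for triggering since
   its onset change is negligible.
2. **Hold and release (hysteresis).** The candidate is accepted only if
   the signal stays within `plateau_tolerance` (1.5 m/s²) of the
   candidate's own plateau estimate for at least `min_plateau_ms`
   (500 ms), and it closes only after all axes settle within
   `offset_return_tolerance` (1.5 m/s²) of rest for `min_return_ms`
   (300 ms). Separate onset/offset bands plus hold times prevent chatter.
   Candidates not separated by a confirmed return merge into one event:
   rapid multi-puffs closer than the return hold are reported as a single
   puff, which is the honest resolution — neither a wrist trace nor video
   can separate them.
3. **Boundary refinement.** Threshold-crossing times depend on the
   threshold, so raw candidate edges would be biased by half a ramp. The
   refiner instead locates the times at which smoothed z crosses 25% and
   75% of the rest-to-plateau span and linearly extrapolates the ramp to
   its corner: for the onset, plateau start = t75 + (t75 − t25)/2, and
   symmetrically for the offset. On noiseless trapezoids this recovers
   plateau edges to within a millisecond (sub-sample, since crossings are
   interpolated between samples); under noise the estimate is unbiased
   because the crossing times are. z is used because its 8 m/s² swing
   gives the best signal-to-noise ratio.

Events are reported in integer milliseconds, sorted, non-overlapping, and
each at least `min_plateau_ms` long. Raising `min_plateau_ms` can only
remove detections, never add them.

If a session consists almost entirely of one sustained plateau, the
quietest-window baseline estimator locks onto that plateau and detection
fails silently; the 20-minute protocol the package targets makes this
configuration unlikely, and it is left unguarded.

## The simulator and what it does (not) emulate

`simulate_session()` reproduces the laboratory protocol: a 20-minute
session (36,000 samples at 30 Hz) containing 6 minutes of smoking split
evenly between hands, 52 seconds of packing the cigarette pack, and over
7 minutes of other movements. The two smoking segments are adjacent — one
continuous smoking block with the hand switch at the midpoint, which is
how a single prompted smoking task plays out — and the ordering and
durations of the remaining segments are a package choice, configurable
via `protocol_schedule()`. Puffs on the non-watch hand appear in the
truth and in the device log but leave the watch-side trace at rest,
mirroring a watch that never changes wrists.

Defaults define the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_puffs_per_hand` | 6 | nominal puffs per 3-minute hand segment |
| PD distribution | log-normal, median 1500 ms, σ = 0.3 | right-skewed positive durations |
| IPI distribution | log-normal, median 20 s, σ = 0.4 | right-skewed positive gaps |
| `rest_pose` | (9, −1, 5) m/s² | back-derived from plateau + onset deltas |
| `plateau_pose` | (9, −5, −3) m/s² | hand-at-mouth hold |
| `transition_ms` | 500 | linear ramp length |
| `noise_sd` | 0.2 m/s² | additive white accelerometer noise |

PD and IPI are drawn log-normal because empirical PD/IPI histograms are
positive and right-skewed; the medians are package choices of realistic
magnitudes, not measured constants. Drawn PDs are floored at 700 ms: a
shorter "puff" is not a credible inhalation (sub-100 ms puffs exist in
device logs only as split artifacts). Drawn IPIs are floored at
2·`transition_ms` + 500 ms so consecutive gestures always fit their
ramps. Cohort simulation adds between-participant log-normal spread
(σ = 0.2) on both medians, Poisson-distributed per-participant puff
counts (clamped to at least 3 and to what the segment can hold given the
participant's IPI median), and completeness flags for emulating recording
failures.

Confounder motions are deliberately stylised: packing is an oscillatory z
perturbation, other movement is narrow-band multi-axis sway. Their only
contract is that they never match the puff signature at zero noise (their
y excursion stays below the onset threshold). They are not biomechanically
realistic wrist motion, and the simulator also omits gravity reorientation
drift, sensor bias, dropped samples, and participant-specific gesture
shapes. Passing the suite therefore demonstrates correctness of the
pipeline's logic under the stated signal model — not field performance on
real wrist data, which only a recorded dataset can establish.

The rest pose deserves a note: published descriptions give the plateau
pose and the onset *deltas*, not the rest pose itself, so the default
rest pose (9, −1, 5) is back-derived as plateau minus deltas and is
configurable per session.

## Device-log cleaning and correction

`clean_cress()` applies two plausibility rules, every action logged with
record indices:

- the leading interval is zeroed when it exceeds
  `leading_ipi_threshold_ms` (default 60 s — intervals over a minute at
  session start are power-on artifacts), or unconditionally under
  `always_drop`;
- records with PD below `min_plausible_pd_ms` are removed. The default
  threshold of 300 ms is a package choice: no credible inhalation is that
  short, while genuine split fragments are shorter by an order of
  magnitude. With `merge_fragments` (default) the fragment's PD and the
  gap separating it from its neighbour are absorbed into the preceding
  record's PD (the following record's, if the fragment is first), which
  reconstitutes the split physical puff and conserves total recorded time
  to the millisecond; plain deletion is retained for sensitivity
  analysis.

`correct_ipis()` implements the corrected-series rule: IPIs flagged as
abnormally short or long are replaced by the arithmetic mean of the
remaining IPIs. Two flagging rules are provided — a fixed plausibility
range (default, 1–120 s) and a robust MAD band (median ± 3 MAD) — because
the selection used in manual corrections of this kind is rarely
specified; every flag is returned, and no fidelity to any particular
annotator's judgment is claimed. Only IPIs are substituted; implausible
PDs are handled in cleaning, where the fragment mechanism that creates
them lives. The substitution preserves list length, is idempotent, and
fails loudly when every IPI is flagged (no reference set remains). The
MAD rule needs at least 3 IPIs; below that the series is returned
unchanged with a warning.

`ccress_pipeline()` composes clean → topography (leading interval
dropped) → substitute, tagging the result `cress_corrected`.

## Agreement statistics

Per participant, PDs are paired by puff index and IPIs by gap index,
truncated to the shorter list, and squared Pearson correlations are
computed per measure. Index pairing (rather than time alignment) is
deliberate: the device log carries no absolute timestamps, and after
window restriction the co-observed stretch is the leading one. Pooled
statistics use per-participant medians for the PD/IPI scatter, puff-count
R² against visual counts (watch versus the watch hand's count, device
versus the two-hand total, since the device sees both hands), and the
proportion of sessions whose counts agree within ±2. Correlation p-values
are not reported; the statistic of interest is the agreement itself.

## Numerical choices and degenerate inputs

- Timestamps are integer milliseconds; sample counts convert via
  `round(n × 1000 / rate)`.
- Sampling-rate inference tolerates the 33/34 ms alternation of a 30 Hz
  grid (gaps within 1 ms or 5% of nominal).
- Medians of even-length lists are the mean of the central pair.
- Histogram bins are left-closed right-open; defaults 250 ms (PD) and
  2 s (IPI).
- Empty inputs: empty event lists produce empty series; empty series
  summarise to `n_puffs = 0` with absent statistics; an empty device log
  cleans to itself with an empty report.
- Cohorts of fewer than 3 participants omit pooled scatter statistics
  with a warning rather than reporting a meaningless correlation, and
  degenerate (constant) count vectors degrade the affected pooled R² to
  `NA` with a warning.
- A single global seed derives per-stage seeds by fixed offsets;
  identical configuration reproduces traces, logs, summaries, and
  manifest checksums bit-exactly.

## Validation problem sizes

The test suite validates zero-noise detection (perfect precision/recall,
boundary error within one sample period) over 100 simulated sessions,
noise robustness (median F1 ≥ 0.95 at 0.5 m/s², 2.5× the default noise)
over 100 sessions, parameter recovery over 40 sessions per noise level,
and correction efficacy (corrected-versus-raw truth agreement) over 100
corrupted logs. `scripts/acceptance.R` recomputes the same quantities at
50-to-100 replicates plus a 35-participant cohort comparison (27 analytic
after 5 device-side and 3 watch-side exclusions). These sizes give stable
medians and proportions while keeping a full run in the tens of seconds.

## Known limitations

- The segmenter assumes the trapezoidal signal model it was designed
  around; gestures with substantially slower or non-monotone transports
  would bias the ramp-extrapolated boundaries.
- Rapid multi-puffs merge into one detected event by design.
- Left/right hand cannot be disambiguated from the signal; the watch hand
  is configuration, not inference.
- Puff volume and flow cannot be derived from wrist accelerometry and are
  carried opaquely from device logs.
- The simulator's confounders are stylised (see above); real-world
  false-positive rates cannot be estimated from it.
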