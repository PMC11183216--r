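# ictalcsd

Laminar current-source-density analysis of ictal discharges.

`ictalcsd` analyses seizures recorded with penetrating laminar
microelectrode arrays — 24 contacts at 150 µm pitch spanning the six
neocortical layers — to determine **which cortical layers generate and
propagate ictal discharges**. It is aimed at epilepsy electrophysiologists
and methods researchers working with dual-band laminar recordings (LFP at
2 kHz, multi-unit band at 20 kHz).

## What it computes

Given a laminar recording with pre-ictal and seizure annotations:

- **CSD**: second spatial derivative of the LFP,
  `CSD_i = (φ_{i−1} − 2φ_i + φ_{i+1}) / h²`, with Vaknin zero-padded
  virtual boundary channels, optional 5-point Hamming spatial smoothing,
  and min–max normalization of sinks to [0, 1] and sources to [−1, 0].
  Sinks are positive: a potential minimum in depth is a current sink.
- **Discharge detection** on the potential-gradient channels by robust-z
  amplitude (4 z), bidirectional slope (0.5 z/ms) and duration
  (20–200 ms) criteria, scored against ground truth by one-to-one
  matching (sensitivity) and 100 ms-binwise specificity.
- **MUA firing rates** by MAD-threshold crossing counting, normalized to
  [0, 1], compared against a 10 s pre-ictal baseline, with the fraction
  of ictal firing carried by the deepest 20% of channels.
- **Layer-group statistics**: per-discharge peak-layer assignment with a
  zone × layer chi-square, sink/source normalized means and variances
  with Welch tests, and the 50 ms sink↔source alternation index.
- **Engagement dynamics**: each seizure normalized to 100 time bins; per
  bin, the distribution across layer groups of |CSD| exceeding baseline
  mean + 2 SD; engagement onsets by a Welch change-point scan.
- **Discharge patterns**: fixed-point ICA (8 components) on
  discharge-triggered 1 s CSD windows, with variance-retention, merge and
  temporal-contiguity rules that count the temporally organized laminar
  patterns (two successive patterns in the ictal onset zone, one outside
  it) and date the switch between them.

A **synthetic laminar-seizure generator** (`simulate_seizure()`) built on
the exact discrete inverse of the CSD estimator provides ground truth for
all of the above: discharge times from a dead-time-corrected renewal
process following the configured rate dynamics (1.3 Hz during the first
second, ramping to 8.9 Hz over 5.3 s, then 7.1 Hz constant, for the
onset zone), prescribed laminar sink/source motifs with polarity
alternation at +50 ms, depth-profiled MUA spike trains, 1/f and mains
noise.

## Worked example

```r
library(ictalcsd)

cfg <- simulation_config(zone = "onset", seed = 1)
sim <- simulate_seizure(cfg)
report <- run_pipeline(cfg)
report
#> <pipeline_report>
#>   detection: 426 events (sens 0.95, spec 0.95)
#>   patterns: 2
#>   MUA deepest-fraction: 0.75
```

The detector recovered 95% of the 429 ground-truth discharges with 95%
binwise specificity; ICA found the two successive laminar discharge
patterns the onset-zone generator embeds; and 75% of
baseline-exceeding multi-unit firing came from the deepest five contacts.
Pattern timing and layer detail:

```r
glance(report$patterns)
#> # A tibble: 1 × 4
#>   n_patterns n_events n_switches first_switch_s
#>        <int>    <int>      <int>          <dbl>
#> 1          2      422          1           15.4
```

The first pattern ends at 15.4 s — 5.4 s after the annotated seizure
onset at 10 s, recovering the generator's configured 5.3 s initiation
phase. `autoplot(...)` methods draw the CSD map, engagement matrix and
MUA rasters; `tidy()`/`glance()` return tibbles for further analysis.

Recordings round-trip through an HDF5 container
(`write_recording()`/`read_recording()`); event tables and engagement
matrices through CSV; the LFP band exports to EDF (16-bit, lossy). A thin
command-line wrapper over the same functions is in
`inst/cli/laminar-pipeline.R`.

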