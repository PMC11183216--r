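---
title: "Laminar CSD analysis of ictal discharges: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar CSD analysis of ictal discharges: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ictalcsd)
```

## The problem

Penetrating laminar microelectrode arrays (here 24 contacts at 150 µm
pitch, spanning ~3.5 mm of neocortex from layer I to layer VI) record two
complementary signals during focal seizures in humans: a low-frequency
local field potential band (LFP, 0.2–500 Hz, 2 kHz sampling) reflecting
summed synaptic currents, and a high-frequency multi-unit band (MUA,
≥300 Hz, 20 kHz) reflecting nearby action-potential firing. The second
spatial derivative of the laminar LFP profile — the current source density
(CSD) — localizes transmembrane current sinks and sources in depth, and
therefore identifies which cortical layers drive each ictal discharge.

`ictalcsd` implements the full analysis chain: band filtering and channel
repair, CSD estimation, automated discharge detection, MUA rate
estimation, layer-group sink/source statistics, engagement dynamics in
normalized seizure time, and ICA-based identification of temporally
organized discharge patterns. Because clinical laminar recordings are not
publicly shareable, the package ships a synthetic seizure generator with
full ground truth; all quantitative claims the test-suite makes are
parameter-recovery statements about that generator.

## The forward model and the CSD estimator

The CSD estimator is the discrete second spatial difference with the
Vaknin boundary treatment (virtual channels above and below the array) and
optional 5-point Hamming spatial smoothing
(`c(0.08, 0.54, 1, 0.54, 0.08) / 2.24`, edge-truncated and renormalized):

$$\mathrm{CSD}_i = \frac{\phi_{i-1} - 2\phi_i + \phi_{i+1}}{h^2},$$

with the sign convention that a potential minimum in depth is a **sink
(positive CSD)**. The generator's forward model is the exact inverse: given
a zero-sum per-contact CSD profile it solves the tridiagonal Dirichlet
problem (zero virtual boundary potentials) so that estimator ∘ forward =
identity to machine precision. This gives every downstream stage a
machine-checkable oracle. The classical Vaknin variant duplicates the edge
channels instead of zero-padding; both are available (`edge_mode`), with
zero-padding the default. Conductivity is never specified for these
arrays, so CSD values are in arbitrary units throughout; all statistics
are either normalized (min–max rescaling of sinks to [0, 1] and sources to
[−1, 0]) or unit-free.

One subtlety: the literal min–max rescaling formula written with an
inverting factor maps the maximum to 0; sinks "normalized between 0 and 1"
with large sinks near 1 require the standard orientation, which is the
default (`invert = TRUE` reproduces the literal inverted form). The
weakest value of each polarity maps exactly onto 0, so zero values stay
zero.

## The synthetic seizure generator

The generator is first-class, tested code: it defines the study conditions
under which every acceptance claim is evaluated.

**Discharge timing.** Seizure phases prescribe a discharge-rate profile.
Onset-zone defaults: a 5.3 s initiation phase whose rate holds at 1.3 Hz
for the first second and then ramps linearly to 8.9 Hz, followed by 57 s
at a constant 7.1 Hz; propagation-zone default: a single 62.3 s phase at
7.1 Hz. Discharges cannot overlap (the waveform occupies 80 ms), so a
plain Poisson process thinned by a dead time would systematically
under-produce the configured rate (at 80 ms dead time it saturates near
4.5 Hz, far below 7.1 Hz). The generator instead draws a
dead-time-corrected renewal process: intervals are
$\tau + \mathrm{Exp}(r/(1 - r\tau))$, whose mean rate is exactly the
configured $r$; the first event of a phase comes from the equilibrium
forward-recurrence distribution so the rate is correct from the first
second. Configured rates must satisfy $r < 1/\tau$, which is validated.

**Discharge waveform.** Each discharge injects
`forward_lfp_from_csd(profile) ⊗ kernel` into the LFP. The kernel is a
raised-cosine lobe over the first 50 ms; at +50 ms — the sink-to-source
alternation lag — a second raised-cosine lobe follows with **inverted
spatial polarity** (probability `alternation_prob`, default 1) and
relative amplitude 0.25. The relative amplitude matters: the detector's
amplitude criterion is a robust z of 4, and the second lobe must stay
below it on every channel or each discharge would be detected twice; 0.25
of a 10-z peak leaves the alternation clearly measurable in the CSD
(≈2 z at the lag) without generating duplicate detections.

**Amplitude calibration.** Discharge amplitude is specified in units of
the noise floor: each motif is scaled so that its largest per-channel
potential-gradient response equals `target_z` (default 10) times that
channel's in-band (0.2–500 Hz) noise SD. Calibrating against the in-band
floor, not the raw 1/f floor, is deliberate: 1/f noise keeps most of its
power below 0.2 Hz, so a detector operating after standard band-limiting
sees roughly half the raw SD, and an amplitude specified against the raw
floor would land at an unintended effective z.

**Laminar motifs.** Onset-zone discharges express two successive motifs
confined to granular and infragranular contacts (12–24): first sinks at
the granular border and the deepest contacts flanking a mid-infragranular
source, then a broad granular/upper-infragranular sink over a deep source.
Keeping the motifs at or below contact 12 is deliberate: 5-point spatial
smoothing spreads energy two contacts upward, and motifs starting at
contact 11 would leak measurable engagement into the supragranular group,
breaking the qualitative contrast the onset zone is defined by.
Propagation-zone discharges carry one supragranular dipole (contacts 1–9)
for the whole seizure, plus a granular component (confined to contacts
11–13, relative amplitude 0.35) switching on at 28% of normalized seizure
time and an infragranular component (0.25) at 42%. The recruited
amplitudes balance two constraints: large enough for the 2-SD engagement
rule to date their onset, small enough that the discharge pattern remains
"one motif" to the ICA merge rule (centroid correlation ≥ 0.9) — the same
tension present in the real phenomenon, where recruitment deepens an
existing pattern rather than replacing it.

**Noise.** Per-channel 1/f (spectrally shaped) noise of configurable SD
plus a mains sinusoid (50/60 Hz) with per-channel gain jitter; no
common-mode term by default. The MUA band holds 1-ms biphasic spike
templates from inhomogeneous Poisson trains (1 Hz spontaneous rate plus
discharge-locked firing shaped by each motif's depth profile, 1 ms
refractory period) in white noise at spike SNR 8. Identical configs
(including the seed) reproduce recordings bit for bit.

What the generator does **not** emulate: spatial correlation of noise
across contacts, non-stationary artifacts, interictal spikes (available as
an option, off by default), electrode drift, seizure termination
dynamics, and any biophysical volume-conduction model. Passing tests
therefore demonstrate correct recovery of the generator's structure, not
clinical performance.

## Discharge detection

Detection runs on the potential-gradient channels (successive-contact
differences, mirroring differential laminar acquisition). Each channel is
converted to a robust z against its pre-ictal baseline (median/MAD over
the annotated ≥10 s pre-ictal window). Candidate events are maximal runs
with |z| above 4; a run is kept if its fastest rising and falling slopes
exceed 0.5 z/ms and its duration lies in [20, 200] ms; runs closer than
50 ms merge. Per-channel events within 25 ms collapse into one discharge
timed at the median per-channel peak. The merge-gap rule is applied once
more across collapsed discharges: detections closer than 50 ms are one
discharge (the strongest wins). This is safe because the generator's
minimum inter-discharge interval is the 80 ms waveform — true neighbours
can never fall inside the merge gap — and it absorbs residual late-lobe
detections that would otherwise double-count a discharge.

Specificity for a point process needs true negatives, so it is defined
binwise over 100 ms bins (bins with no true event are negatives; a
negative bin containing a detection is a false positive). Precision and
false alarms per minute are reported alongside.

## Layer statistics and engagement

Contacts map to supragranular (1–10), granular (11–13) and infragranular
(14–24) groups by default, approximating human cortical proportions at
150 µm pitch; the boundaries are configurable because contact-to-layer
assignment is recording-specific. Peak-layer assignment searches ±25 ms
around each event peak, ties go to the deepest contact, and the 2×3
zone-by-layer table is tested with Pearson's chi-square (exact-test
fallback below expected counts of 5). Sink/source summaries use Welch
tests across recordings, tolerant of zero-variance degenerate samples.
The alternation index is the fraction of events whose CSD changes sign
between the event time and +50 ms, with events below one robust SD of the
baseline CSD excluded from the denominator.

Engagement analysis normalizes each seizure to 100 equal-duration bins
(the last bin absorbs the integer remainder; a uniform time-stretch leaves
the matrix invariant up to discretization). Per contact and bin, the
engagement is the excess of mean |CSD| over baseline mean + 2 SD (baseline
binned at the same bin duration); `binary = TRUE` counts outliers instead
of summing excess, as both readings of "summation of the resultant values"
are defensible. Bins are then normalized to a distribution across
contacts or layer groups. Engagement onset is estimated with a
change-point scan: every split k ∈ [5, 95] is scored by a Welch t test of
bins ≤ k against bins > k, and the onset is the first late bin of the
most significant split with a late-segment increase (α = 0.01). Taking
the *most significant* split rather than the earliest significant one is
essential: a clean step at bin 30 already separates significantly at
k = 5, but the t statistic is maximized — infinite, in the noiseless
case — exactly at the true boundary.

## ICA discharge patterns

Each detected discharge contributes a 1 s CSD window centred on its peak,
normalized by its own max |CSD| and weighted by a Gaussian temporal taper
(SD 50 ms). The taper addresses a structural problem: at ictal rates a
1 s window contains ~7 neighbouring discharges at random offsets, and
their placement jitter dominates the untapered window variance, drowning
the aligned central discharge that actually identifies the motif.

The decomposition whitens the event × features matrix by **uncentered**
PCA to 8 dimensions and rotates with fixed-point ICA (the `ica` package's
FastICA implementation, deterministically initialised from the provided
seed). Uncentered is a considered choice: discharges express one laminar
motif at a time, so motif identity is a sparse, non-negative activation —
each motif is a ray from the origin. Mean-centering mutually exclusive
motifs collapses them onto a single difference axis on which both groups
load with opposite signs, which no magnitude-based assignment can
separate. Components are ordered by explained variance of the uncentered
second moment.

Pattern counting retains components with a variance share ≥ 0.01, assigns
each event to the component contributing the most energy to its window
(|loading| weighted by the component's energy scale — in whitened units
all components are artificially equal), merges components whose mean
assigned-window correlation is ≥ 0.9 (single linkage), and accepts a
merged group as a pattern when it covers ≥ 2% of events and is temporally
contiguous (≥ 80% of the events inside the group's decile-trimmed time
interval belong to the group). Non-contiguous candidates are reported and
flagged, not counted. The variance-retention and support defaults are
lower than a first guess would suggest because the onset-zone initiation
phase is short: ~20 discharges against ~400, i.e. ~5% support and a few
percent of variance; thresholds of 5%/10% would define the initiation
pattern out of existence. Switch times between adjacent patterns are the
midpoint of the optimal 1-D separation boundary between their event
times, which is robust to a few misassigned events deep in the other
epoch.

## Multi-unit activity

MUA is quantified by threshold-crossing counting (4 × MAD, 1 ms
refractory), binned at 10 ms, smoothed with a 100 ms boxcar and min–max
normalized per recording (per channel optionally — the analysis-level
choice is not derivable from first principles, so both are exposed). The
depth statistic is the fraction of baseline-exceeding firing carried by
the deepest ⌈0.2·n⌉ channels, with negative ictal-minus-baseline excesses
floored at zero.

## Numerical choices and degenerate inputs

- Filters are Butterworth applied forward–backward (zero phase): 4th
  order, except the 0.2 Hz LFP high-pass which is 2nd order — at 10⁻⁴ of
  Nyquist a 4th-order design is numerically fragile while the 2nd-order
  one is both stable and sufficient for DC removal.
- Bad channels interpolate linearly in depth between nearest good
  neighbours (distance-weighted); edge channels copy their nearest good
  neighbour; a guard refuses when more than 25% of channels are bad.
- An all-zero CSD rescales to all zeros with a warning rather than
  dividing by a degenerate range.
- Welch tests on zero-variance segments return p = 0 for a mean shift and
  p = 1 otherwise instead of failing.
- Event ties in |CSD| resolve to the deepest contact, deterministically.
- The single pipeline seed fans out to per-stage child seeds by stable
  hashing of the stage name, so adding a stage never perturbs another
  stage's stream.

## Problem sizes used by the test-suite

The packaged checks run the default onset-zone condition at full length
(10 s baseline + 5.3 s + 57 s) for 10 seeds with the complete pipeline,
extend the detected-rate sample to 50 seeds with detection only, run 20
propagation-zone seizures for engagement-onset recovery (8 at full
analysis in the test-suite, 20 in the acceptance script), and 2 full
dual-band simulations for the MUA depth statistic. Unit tests use a
shortened second phase (12 s) where phase structure is irrelevant. These
sizes keep the Monte-Carlo standard errors comfortably inside the stated
tolerances (e.g. the 50-seed mean of the first-second discharge count has
an SEM near 0.16 against a ±0.4 band).

## Known limitations

- The ICA pattern count is a statement about motif exclusivity and epoch
  structure; seizures expressing two motifs *simultaneously* would
  require a different (e.g. convolutive) decomposition.
- Engagement onsets assume a single upward change point per group; ramps
  are dated near their steepest sustained rise, not their first sample.
- The EDF export quantizes to 16 bits per channel range and is lossy by
  construction; the HDF5 container is the lossless interchange format.
- Specificity depends on the 100 ms bin convention; per-event precision
  is reported alongside for a bin-free view.
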