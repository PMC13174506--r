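---
title: "Methods: directional connectivity analysis for organoid microchannels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: directional connectivity analysis for organoid microchannels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonflux)
```

## The problem

Two region-specific neural organoids connected by a micropatterned
microchannel form a minimal model of a directed interregional projection.
Asymmetric channel geometries let axons grow through in one (permissive)
direction while trapping growth cones travelling the other way. Two
measurements characterise the resulting circuit:

1. **Electrophysiology.** Electrodes at a fine pitch (17.5 µm) line the
   channel on a high-density MEA. An action potential travelling along an
   axon in the channel appears as a sequence of spikes at successive
   electrodes with latencies proportional to distance. Directional channels
   should show propagation in only one orientation, and an excess of firing
   near the channel exit where axons from both organoids accumulate.
2. **Imaging.** Hourly growth-cone positions (tracks) and axial
   fluorescence profiles quantify how far and how fast neurites grow in
   each channel orientation.

`axonflux` implements both analyses and a synthetic-data module that
emulates the recordings, so the whole chain is testable end to end.

## Spike detection

Each electrode's trace is thresholded at
`rms_threshold_multiple × RMS(trace)` (default 3.5). Within a contiguous
supra-threshold run of `|v|`, only the largest-magnitude sample is
reported; the event time is that sample over the sampling rate and the
amplitude the signed voltage there. Events closer than `isi_min_s`
(default 1 ms) to the last kept event are removed greedily, earliest
first, so every surviving gap is at least the minimum ISI. Firing rate is
`count / duration`.

Choices worth noting:

- Detection uses `|v|`, both polarities, because only a threshold multiple
  is specified for the procedure; extracellular spikes are
  negative-dominant, and absolute-value detection handles either
  convention symmetrically.
- The RMS is computed over the whole raw trace with no band-pass by
  default (`rms_method = "rms"`); a robust MAD/0.6745 estimate is
  available as `rms_method = "mad"`. Synthetic traces have no drift, so
  filtering is unnecessary there.
- A plain 3.5σ threshold on a 20 kHz Gaussian trace yields isolated false
  crossings at a few hertz. These do not survive the propagation guards
  (below): chance events almost never produce 30 paired events inside a
  1 ms-wide window, and never at > 80% co-occurrence. The detector is
  therefore used as specified rather than augmented with extra rejection
  rules.

## Propagation reconstruction

For a channel, source and target electrodes default to the member
electrodes nearest the entry and exit endpoints. Scanning source events in
time order, each is paired with the earliest unused target event whose
latency lies in the **closed** window `[1, 2]` ms; each target event is
used at most once. A pairing qualifies with at least 30 pairs. Greedy
earliest-unused-target matching on a fixed-width window attains the
maximum possible pair count (the classic interval-matching argument); the
test suite cross-checks this against an independent maximum-bipartite-
matching oracle.

Electrodes are mapped onto the principal axis (the straight line from
entry to exit): signed axial projection, axial fraction, and unsigned
orthogonal offset. Intermediary candidates must lie within the orthogonal
search band (`band_half_width_um`, default 17.5 µm, *inclusive* so the
adjacent electrode row at exactly one pitch is captured) and strictly
between the endpoints. For each anchor fraction (25/50/75 %), among
candidates whose co-occurrence fraction strictly exceeds 0.80 — the
fraction of closed paired windows `[t_source, t_target]` containing at
least one candidate event — the electrode with axial fraction closest to
the anchor is chosen; equidistant ties go to the smaller electrode id;
anchors with no passing candidate are skipped.

The latency trace orders source (latency 0), intermediaries (median over
windows of the first in-window candidate event minus the source time),
and target (median pair latency) by axial position. Conduction velocity is
the slope of ordinary least squares of axial position (mm) on latency
(ms). With only source and target the fit degenerates to the two-point
slope; a zero latency spread is an error. A channel orientation is
*qualified* when its pairing qualifies and a finite positive velocity is
fitted; the two orientations combine into `forward_only`,
`backward_only`, `both`, or `none`.

## Flux statistics

Quartiles are half-open bins of axial fraction (`[0, 0.25)` is Q1;
fraction 1 closes into Q4), defined on distance rather than electrode
index so irregular electrode subsets bin sensibly. The quartile rate is
the unweighted mean of its electrodes' rates, making the electrode the
sampling unit — consistent with the Mann–Whitney comparison of Q1 vs Q4
electrode rates. The **flux ratio** is `FR(Q4) / FR(Q1)`; a channel whose
entry quartile is essentially silent (< 1e-6 Hz) yields an undefined
ratio that is excluded (and counted) rather than clamped. Profiles use 5 %
axial bins normalized by the Q1 mean; empty bins are flagged, never
zero-filled, and the electrode-count-weighted mean of the Q1 bins is 1 by
construction.

The per-channel asymmetry test is two-sided Mann–Whitney on the Q1 vs Q4
electrode rates, exact by enumeration when both sides have ≤ 12
observations and no ties, otherwise the normal approximation with tie and
continuity correction. No multiple-testing correction is applied across
channels by default (per-channel α = 0.05, replicating the study's
procedure); `condition_summary()` accepts any `p.adjust` method for
sensitivity analyses.

One boundary subtlety: with half-open bins, an electrode sitting exactly
on a quartile boundary (fraction 0.25 or 0.75, as happens in a
910 µm / 17.5 µm layout) changes quartile when the axis is reflected, so
the flux-ratio inversion identity `FR_forward × FR_reversed = 1` is exact
only for layouts without exact-boundary electrodes (e.g. 900 µm at
17.5 µm pitch). The property suite uses such a layout.

## What the generator emulates — and what it does not

`simulate_channel_dataset()` builds a collinear channel layout
(`floor(length/pitch) + 1` electrodes) and two axon populations:

- the **proximal** population spans the whole channel at
  `proximal_rate_hz` per electrode (default 2.6 Hz);
- for directional channels, a **distal** population at `distal_rate_hz`
  (default 5.1 Hz) occupies the exit-side `distal_extent_fraction`
  (default 0.5) — the crossover point is not constrained by imaging, so
  the symmetric half-channel choice is the default and configurable. The
  exit quartile then totals 7.7 Hz against 2.6 Hz at the entry, the
  representative asymmetry.

Each population's rate is split: a fraction `propagation_fraction`
(default 0.4) is carried by propagating spike sequences — source events
re-emitted at every electrode along the propagation direction with delay
`distance / velocity` (default 650 µm/ms = 0.65 mm/ms), optional Gaussian
jitter, and optional dropout — and the remainder is independent
per-electrode Poisson background. Per-electrode totals therefore stay at
the stated rates while propagation remains detectable and per-electrode
counts keep Poisson variability. Straight channels split the propagating
share equally between the two directions, making them statistically
symmetric under axial reflection.

Raw traces are rendered by adding a fixed biphasic template (1 ms
support, trough at the event amplitude, default −60 µV) at the sample
nearest each event, on Gaussian noise (default 5 µV sd). The template
shape is irrelevant to downstream logic and fixed for reproducibility;
overlapping events sum. Every generator is a pure function of
(configuration, seed), with per-electrode/per-population substreams so
adding electrodes does not reshuffle existing trains.

Neurite tracks are cumulative sums of non-negative hourly steps
(Gaussian truncated at zero, capped at the channel length) at
11.4 µm/hr (permissive) vs 2.9 µm/hr (prohibitive), the study's mean
outgrowth rates, over 16 hourly observations for 97 and 90 tracks. Step
sds default to 4.0 and 1.0 µm/hr: small enough relative to the means that
zero-truncation biases the realised mean by < 0.5 %, so cohort means
recover the nominal rates within sampling error at those n. The reported
dispersion statistics for the tracked cohorts are internally inconsistent
(a coefficient of variation of 1.6 would contradict the stated standard
errors), so the generator does not adopt them. Intensity profiles count,
at each axial position, the tracks whose tip has passed it, scaled to
arbitrary units.

Deliberately **not** modelled: biophysical cable properties, spike
waveform diversity or sorting, electrode drift and LFP, curved channel
axes, branching or multi-path propagation, image segmentation, and the
full 26,400-electrode array (only channel-restricted subsets are
generated). Passing tests on this generator therefore validate the
analysis logic and its boundary rules — not robustness to waveform
overlap, drift, or non-Poisson firing statistics of real tissue.

## Neurite quantification choices

- Track velocity is net displacement over elapsed time, not the mean of
  per-hour increments: it matches mean displacement as a function of time
  and is robust to missed frames.
- Traversal extent thresholds the profile at background mean + 3 SD; the
  background window is the distal 5 % of a reference profile (the profile
  itself by default; pass a neurite-free reference such as the
  prohibitive-side profile when signal spans the entire channel). Adding
  signal outside the background window can only increase the extent;
  signal added inside it raises the threshold, which is why the reference
  is configurable.
- Full crossing is ≥ 95 % of channel length rather than literally 100 %,
  allowing for pixelation of fluorescence at the channel exit;
  configurable.
- Group comparisons: two-sided Welch t for pairs; Dunnett many-to-one
  single-step adjustment against a named control on an ANOVA fit, with
  the unadjusted per-comparison p-values reported alongside.

## Numerical conventions and degenerate inputs

Times are seconds (double), positions µm, voltages µV, velocities quoted
in mm/ms (1 mm/ms = 1 µm/µs = 1 m/s × 10³). Spike tables sort
canonically by (electrode, time), ties in time broken by amplitude
descending, so writes are deterministic and diffable. Files embed a
format version and loaders reject unknown versions rather than guess.
Recording containers are HDF5 (single-precision signals; round-trips are
exact for spike tables and channel specs, within float32 rounding for
signals, i.e. < 1e-3 µV below 1 kµV). Empty spike tables, silent
quartiles, all-dropout injections, and two-point latency traces are all
defined cases rather than errors; coincident axis endpoints, unsorted
event times, zero durations and zero latency spreads are errors naming
the offending input.

## Test problem sizes

The suite favours sizes that exercise the statistics without waste:
detection oracles run on 2,000-sample traces; pairing oracles on ≤ 20×20
event sets; type-I error of the asymmetry test on 1,200 null channels of
Poisson-count rates (13 vs 14 electrodes, 2 Hz, 60 s equivalent); power
at the study effect size (2.6 vs 7.7 Hz, 600 s) on 50 seeds; straight-
channel flux calibration on 50 simulated 600 s channels; neurite cohorts
at the study's 97/90 tracks. End-to-end rendered recordings use shorter
durations (tens of seconds) and, where pitch is irrelevant to the logic
under test, coarser pitches, because dense-trace memory scales as
electrodes × samples while every decision rule is pitch- and
duration-agnostic.
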