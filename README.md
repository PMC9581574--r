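# lfpmon

Headless analysis tooling for **chronic multianimal video-LFP seizure
monitoring**. Low-cost acquisition rigs (Intan headstages + an Open Ephys
board, orchestrated by a visual dataflow program) record bilateral
hippocampal local field potentials from up to four epileptic mice at once,
save hour-long binary segments, and pair every 256-sample voltage packet with
the index of the most recent ~30 Hz video frame. `lfpmon` re-implements the
computational core of that platform for people who need to analyse such
sessions reproducibly and in bulk, without the interactive GUI:

* **Session I/O** — packet-blocked 16-bit unsigned amplifier files, 32-bit
  unsigned timestamp files (per packet: 256 sample timestamps + 256 repeats
  of the assigned frame index), JSON session configs, chronological segment
  discovery, and raw-to-microvolt scaling (0.195 µV/bit).
* **Synchronization** — packet↔frame maps, offline linear interpolation of
  unassigned frames, per-gap statistics, and sample-continuity checking
  within and across hour segments.
* **Two seizure detectors.** *Amplitude*: downsample to 500 Hz, zero-phase
  bandpass 3–50 Hz, threshold at `mean + N·SD`, group supra-threshold peaks
  firing at ≥ 3 Hz into bursts, merge bursts within 2.5 s, keep events
  longer than a user minimum. *Spectral*: 128-point sliding-window FFT,
  power averaged over 4–40 Hz, thresholded and post-processed identically.
* **Independence QC** — pairwise Pearson correlations of hour-long traces in
  three categories (within-mouse L/R same hour; across mice same hour;
  across mice different hours), empirical CDFs, one-way ANOVA with Tukey
  post hoc — the standard check that simultaneously recorded animals do not
  bleed into each other's channels.
* **Scoring data model** — the three-question event questionnaire
  (true/false positive + continuation; hemisphere; Racine stage or
  subclinical), per-scorer JSON annotation files, validation summaries
  (false-positive rate, subclinical vs behavioral counts), inter-scorer
  agreement, and ground-truth interval matching.
* **Synthetic sessions** — a seeded generator (1/f background with
  controllable within-animal L/R coupling, interictal spikes, seizure spike
  trains, movement artifacts, asynchronous packet/frame timing) that writes
  the full binary footprint, so every stage above runs end-to-end with no
  recordings.

The detection model in brief: with `x(t)` the downsampled (and, for the
amplitude method, 3–50 Hz bandpassed) detection trace, the threshold is
`θ = mean(x) + N·sd(x)`; local maxima above θ are peaks; consecutive peaks
with inter-peak interval ≤ 1/3 s form bursts; bursts separated by ≤ 2.5 s are
merged; merged bursts spanning ≥ `min_duration_s` become events with onset and
offset at their first/last peak. Both detectors are invariant to rescaling the
input, by construction.

## Worked example

```r
library(lfpmon)

# 1. simulate a 2-min session of two mice, one bilateral seizure in mouse 1
spec <- simulation_spec(
  seed = 42, duration_s = 120, n_animals = 2,
  seizures = data.frame(animal = 1, start_s = 45, duration_s = 8,
                        spike_rate_hz = 8, amplitude_uv = 500, bilateral = TRUE))
gen <- generate_signals(spec)
records <- simulate_frame_assignment(spec)
write_session(gen$signals, records, spec, "session", segment_length_s = 60,
              truth = gen$truth)

# 2. read it back like any recorded session
config <- parse_config(file.path("session", "config.json"))
manifest <- discover_session("session", config)
manifest$segment_label
#> [1] "2022-01-01T00-00-00" "2022-01-01T00-01-00" "2022-01-01T00-02-00"

# 3. amplitude-threshold detection on mouse 1's left channel
uv <- scale_to_microvolts(read_amplifier(manifest$amplifier_path[1], config), config)
settings <- detection_settings(threshold_n_sd = 5, min_duration_s = 3)
events <- detect_amplitude(uv[1, ], settings, config$sample_rate_hz, channel = 0)
as.data.frame(events)[, c("onset_s", "offset_s", "duration_s", "n_peaks")]
#>   onset_s offset_s duration_s n_peaks
#> 1  45.004   53.004          8      65

# 4. synchronization QC: frame-assignment gaps and sample continuity
recs <- lapply(manifest$timestamp_path, read_timestamp_file, config = config)
gap_statistics(build_sync_map(recs[[1]]))$mean
#> [1] 2.841542
check_continuity(recs, manifest$segment_label)
#> <continuity_report> 0 gap(s), 0 missing sample(s)

# 5. packet bookkeeping (1-based, report convention)
unlist(packet_sample_range(5, config))
#> first_sample  last_sample     first_ms      last_ms
#>         1025         1280          513          640
```

Reading the output: the scheduled 8 s seizure at 45 s is recovered with onset
and offset at its first/last detected peak (45.0–53.0 s, 65 peaks of the 8 Hz
spike train and its filter ringing). The mean frame-assignment gap of ≈ 2.84
frames is what a 30 Hz camera paired with 128 ms voltage packets implies
(128 / 33.3 − 1); packet 5 spans samples 1025–1280, i.e. 513–640 ms at 2 kHz.

A command-line wrapper with `simulate`, `detect`, `sync-report`, `qc`,
`summarize` and `agreement` subcommands is installed at
`inst/cli/lfpmon` (see `lfpmon_main()`).

## Scope

The package is the computational core only: it does not decode video files
(frame indices are the interface), talk to acquisition hardware, reproduce
the interactive GUI, or attempt onset/offset refinement beyond the detectors'
peak extremes. See `vignettes/lfpmon-methods.Rmd` for the model, parameter
and design rationale, and the limits of what the synthetic world establishes.
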