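# Synthetic multianimal session generator.
#
# The generator states a world resembling chronic bilateral hippocampal LFP
# in epileptic mice: 1/f background noise with a shared within-animal
# component, sparse interictal spikes, scheduled seizures as regular trains
# of large biphasic spikes, and broadband movement artifacts
# (grooming/eating-like). It also simulates the asynchronous pairing of
# 256-sample voltage packets with ~30 Hz video frames, and writes the full
# binary file footprint so every reader in the package can be exercised
# without recordings.

#' Specify a synthetic session
#'
#' @param seed Integer; fully determines the generated session.
#' @param duration_s Session length in seconds (truncated to whole packets).
#' @param n_animals Number of animals (2 channels each).
#' @param noise_sd_uv Background noise SD in microvolts (default 25, a typical
#'   awake-LFP background after referencing).
#' @param one_over_f_exponent Spectral slope of the background (power ~
#'   1/f^a, default 1: pink noise).
#' @param shared_source_mixing Fraction of within-animal L/R variance drawn
#'   from a common source, in `[0, 1]` (default 0.5: moderate interhemispheric
#'   correlation).
#' @param interictal_rate_hz Poisson rate of interictal spikes per channel
#'   (default 0.05 Hz, a few per minute).
#' @param interictal_amplitude_uv Interictal spike amplitude (default 300).
#' @param spike_width_ms Width of the biphasic spike waveform (default 30).
#' @param seizures Data.frame (or list of lists) with columns `animal`,
#'   `start_s`, `duration_s`, `spike_rate_hz`, `amplitude_uv`, `bilateral`.
#' @param artifacts Data.frame with columns `animal`, `start_s`, `duration_s`,
#'   `kind` (`"grooming"` or `"eating"`), `amplitude_uv`; broadband bursts on
#'   both channels of the animal.
#' @param sample_rate_hz,samples_per_packet Acquisition constants.
#' @param frame_period_ms Video frame period (default 1000/30).
#' @param packet_emit_latency_ms Constant latency between a packet's last
#'   sample and its arrival at the synchronizer.
#' @param frame_latency_jitter_ms Uniform jitter on frame timestamps.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L,
                            duration_s = 60,
                            n_animals = 1L,
                            noise_sd_uv = 25,
                            one_over_f_exponent = 1,
                            shared_source_mixing = 0.5,
                            interictal_rate_hz = 0.05,
                            interictal_amplitude_uv = 300,
                            spike_width_ms = 30,
                            seizures = NULL,
                            artifacts = NULL,
                            sample_rate_hz = 2000,
                            samples_per_packet = 256L,
                            frame_period_ms = 1000 / 30,
                            packet_emit_latency_ms = 0,
                            frame_latency_jitter_ms = 0) {
  as_df <- function(x, cols) {
    if (is.null(x)) return(NULL)
    df <- if (is.data.frame(x)) x else do.call(rbind, lapply(x, as.data.frame))
    missing <- setdiff(cols, names(df))
    if (length(missing)) {
      lfp_abort(sprintf("schedule missing column(s): %s", paste(missing, collapse = ", ")),
                "lfpmon_spec_error")
    }
    df
  }
  seizures <- as_df(seizures, c("animal", "start_s", "duration_s",
                                "spike_rate_hz", "amplitude_uv", "bilateral"))
  artifacts <- as_df(artifacts, c("animal", "start_s", "duration_s", "kind", "amplitude_uv"))
  if (!is.null(seizures) && nrow(seizures)) {
    if (any(seizures$start_s < 0 | seizures$start_s + seizures$duration_s > duration_s)) {
      lfp_abort("seizure schedule outside [0, duration_s]", "lfpmon_spec_error")
    }
    for (an in unique(seizures$animal)) {
      s <- seizures[seizures$animal == an, ]
      s <- s[order(s$start_s), ]
      if (nrow(s) > 1 && any(s$start_s[-1] < (s$start_s + s$duration_s)[-nrow(s)])) {
        lfp_abort(sprintf("overlapping seizures scheduled for animal %s", an), "lfpmon_spec_error")
      }
    }
  }
  if (!is.null(artifacts) && nrow(artifacts) &&
      any(artifacts$start_s < 0 | artifacts$start_s + artifacts$duration_s > duration_s)) {
    lfp_abort("artifact schedule outside [0, duration_s]", "lfpmon_spec_error")
  }
  if (shared_source_mixing < 0 || shared_source_mixing > 1) {
    lfp_abort("shared_source_mixing must be in [0, 1]", "lfpmon_spec_error")
  }
  structure(list(seed = as.integer(seed), duration_s = duration_s,
                 n_animals = as.integer(n_animals),
                 noise_sd_uv = noise_sd_uv,
                 one_over_f_exponent = one_over_f_exponent,
                 shared_source_mixing = shared_source_mixing,
                 interictal_rate_hz = interictal_rate_hz,
                 interictal_amplitude_uv = interictal_amplitude_uv,
                 spike_width_ms = spike_width_ms,
                 seizures = seizures, artifacts = artifacts,
                 sample_rate_hz = sample_rate_hz,
                 samples_per_packet = as.integer(samples_per_packet),
                 frame_period_ms = frame_period_ms,
                 packet_emit_latency_ms = packet_emit_latency_ms,
                 frame_latency_jitter_ms = frame_latency_jitter_ms),
            class = "simulation_spec")
}

# biphasic spike: sharp positive lobe followed by a slower, shallower
# negative lobe; bandpass-surviving shape without claiming morphology
spike_waveform <- function(width_ms, fs, amplitude) {
  n <- max(3L, round(width_ms / 1000 * fs))
  n_pos <- max(2L, round(n / 3))
  n_neg <- n - n_pos
  pos <- sin(pi * seq(0, 1, length.out = n_pos))
  neg <- -0.4 * sin(pi * seq(0, 1, length.out = n_neg))
  amplitude * c(pos, neg)
}

# 1/f^a noise by a cascade of first-order pole-zero sections with
# geometrically spaced poles (two per decade between f_low and fs/2) and
# zeros offset by a/2 of the pole spacing -- the classic linear-time
# approximation to a power-law spectrum (ripple well under 1 dB over the
# band of interest). White noise for a = 0.
one_over_f_noise <- function(n, exponent, sd_target, fs = 2000, f_low = 0.1) {
  w <- stats::rnorm(n)
  if (exponent == 0 || sd_target == 0) return(w * sd_target)
  per_decade <- 2
  decades <- log10((fs / 2) / f_low)
  fp <- f_low * 10^(seq(0, decades, by = 1 / per_decade))
  fz <- fp * 10^((exponent / 2) / per_decade)
  p0 <- exp(-2 * pi * fp / fs)
  z0 <- exp(-2 * pi * pmin(fz, fs / 2) / fs)
  b <- Re(poly_from_roots(z0))
  a <- Re(poly_from_roots(p0))
  x <- iir_filter(b, a, w)
  x * sd_target / stats::sd(x)
}

# sum of waveforms at given onsets as one sparse accumulation: returns the
# (index, value) pairs to add, avoiding any full-trace copies in the caller
pulse_train_delta <- function(n, start_idx, w) {
  if (!length(start_idx)) return(list(idx = integer(0), val = numeric(0)))
  idx <- as.vector(outer(seq_along(w) - 1L, as.integer(start_idx), `+`))
  val <- rep(w, times = length(start_idx))
  keep <- idx >= 1L & idx <= n
  idx <- idx[keep]; val <- val[keep]
  if (anyDuplicated(idx)) {   # overlapping waveforms must sum, not overwrite
    agg <- rowsum(val, idx)
    idx <- as.integer(rownames(agg)); val <- as.vector(agg)
  }
  list(idx = idx, val = val)
}

#' Generate the microvolt signals of a synthetic session
#'
#' Background is 1/f-shaped Gaussian noise; within an animal the left/right
#' channels mix an independent and a shared source so their correlation is
#' controlled by `shared_source_mixing`, while different animals are fully
#' independent. Interictal spikes arrive as a Poisson process per channel;
#' scheduled seizures are regular biphasic-spike trains (both channels when
#' `bilateral`); artifacts are broadband noise bursts on both channels.
#' Everything is drawn from one generator seeded by `spec$seed` in a fixed
#' order, so output is reproducible bit for bit.
#'
#' @param spec A [simulation_spec()].
#' @return List with `signals` (`[2*n_animals x n_samples]` microvolt matrix,
#'   rows = animal-major L,R pairs) and `truth` (a `ground_truth` list:
#'   per-channel seizure and artifact intervals and interictal spike times).
#' @export
generate_signals <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  fs <- spec$sample_rate_hz
  P <- spec$samples_per_packet
  n <- (floor(spec$duration_s * fs) %/% P) * P
  n_ch <- 2L * spec$n_animals
  set.seed(spec$seed)
  # channel traces are built as local vectors (in-place modification) and
  # assembled into the matrix once at the end
  chans <- vector("list", n_ch)
  m <- spec$shared_source_mixing
  for (a in seq_len(spec$n_animals)) {
    shared <- one_over_f_noise(n, spec$one_over_f_exponent, spec$noise_sd_uv, fs)
    for (side in 1:2) {
      own <- one_over_f_noise(n, spec$one_over_f_exponent, spec$noise_sd_uv, fs)
      x <- sqrt(1 - m) * own + sqrt(m) * shared
      if (spec$noise_sd_uv == 0) x[] <- 0
      chans[[2L * (a - 1L) + side]] <- x
    }
  }
  interictal <- vector("list", n_ch)
  w_ii <- spike_waveform(spec$spike_width_ms, fs, spec$interictal_amplitude_uv)
  for (ch in seq_len(n_ch)) {
    n_spk <- stats::rpois(1, spec$interictal_rate_hz * n / fs)
    t_spk <- sort(stats::runif(n_spk, 0, n / fs))
    interictal[[ch]] <- t_spk
    d <- pulse_train_delta(n, round(t_spk * fs) + 1L, w_ii)
    x <- chans[[ch]]
    x[d$idx] <- x[d$idx] + d$val
    chans[[ch]] <- x
  }
  seiz_truth <- list()
  if (!is.null(spec$seizures) && nrow(spec$seizures)) {
    for (i in seq_len(nrow(spec$seizures))) {
      s <- spec$seizures[i, ]
      w <- spike_waveform(spec$spike_width_ms, fs, s$amplitude_uv)
      t_spikes <- seq(s$start_s, s$start_s + s$duration_s, by = 1 / s$spike_rate_hz)
      on_ch <- 2L * (s$animal - 1L) + if (isTRUE(s$bilateral)) 1:2 else 1L
      d <- pulse_train_delta(n, round(t_spikes * fs) + 1L, w)
      for (ch in on_ch) {
        x <- chans[[ch]]
        x[d$idx] <- x[d$idx] + d$val
        chans[[ch]] <- x
      }
      seiz_truth[[i]] <- data.frame(animal = s$animal, channels = I(list(on_ch)),
                                    start_s = s$start_s,
                                    end_s = s$start_s + s$duration_s)
    }
  }
  if (!is.null(spec$artifacts) && nrow(spec$artifacts)) {
    for (i in seq_len(nrow(spec$artifacts))) {
      a <- spec$artifacts[i, ]
      i0 <- round(a$start_s * fs) + 1L
      len <- round(a$duration_s * fs)
      burst <- stats::rnorm(len) * a$amplitude_uv
      env <- sin(pi * seq(0, 1, length.out = len))   # taper the burst
      idx <- i0 + seq_len(len) - 1L
      keep <- idx >= 1L & idx <= n
      for (ch in 2L * (a$animal - 1L) + 1:2) {
        x <- chans[[ch]]
        x[idx[keep]] <- x[idx[keep]] + (burst * env)[keep]
        chans[[ch]] <- x
      }
    }
  }
  sig <- do.call(rbind, chans)
  truth <- structure(list(
    seizures = if (length(seiz_truth)) do.call(rbind, seiz_truth) else NULL,
    artifacts = spec$artifacts,
    interictal_spike_times = interictal), class = "ground_truth")
  list(signals = sig, truth = truth)
}

#' Simulate the packet-to-frame assignment of the acquisition rig
#'
#' Packet `k` (0-based) finishes at `(k+1) * P / fs` seconds and arrives at
#' the synchronizer `packet_emit_latency_ms` later; it is assigned the index
#' of the most recent video frame whose (jittered) timestamp is at or before
#' that arrival. Frames are numbered from 1 at time 0, matching the live
#' numbering of the acquisition workflow. Jitter never reorders frames (it is
#' bounded below the frame period in the spec's stated worlds).
#'
#' @param spec A [simulation_spec()].
#' @return A `packet_records` data.frame (timestamps start at 0).
#' @export
simulate_frame_assignment <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  fs <- spec$sample_rate_hz
  P <- spec$samples_per_packet
  n_packets <- floor(spec$duration_s * fs) %/% P
  set.seed(spec$seed + 1L)   # independent of the signal draw
  packet_arrival_ms <- (seq_len(n_packets) * P / fs) * 1000 + spec$packet_emit_latency_ms
  n_frames <- ceiling(max(packet_arrival_ms) / spec$frame_period_ms) + 2L
  frame_time_ms <- (seq_len(n_frames) - 1L) * spec$frame_period_ms
  if (spec$frame_latency_jitter_ms > 0) {
    frame_time_ms <- frame_time_ms +
      stats::runif(n_frames, 0, spec$frame_latency_jitter_ms)
    frame_time_ms <- cummax(frame_time_ms)  # jitter must not reorder frames
  }
  # +1e-6 ms keeps exact frame/packet coincidences inclusive ("at or before")
  # against floating-point rounding of the frame grid
  frame_idx <- findInterval(packet_arrival_ms + 1e-6, frame_time_ms)
  frame_idx <- pmax(frame_idx, 1L)
  new_packet_records(seq_len(n_packets) - 1L,
                     (seq_len(n_packets) - 1L) * P,
                     frame_idx, P)
}

#' Write a synthetic session to disk
#'
#' Quantizes the microvolt signals to 16-bit raw units around mid-range
#' (32768), splits signals and packet records into `segment_length_s`
#' segments, and writes per-segment amplifier and timestamp files with
#' chronologically sortable labels, plus the session `config.json` and a
#' `ground_truth.json` sidecar. Listed packets can be dropped from both
#' streams to inject continuity gaps.
#'
#' @param signals Microvolt matrix from [generate_signals()].
#' @param records `packet_records` from [simulate_frame_assignment()].
#' @param spec The [simulation_spec()].
#' @param out_dir Output directory (created).
#' @param segment_length_s Segment length (default one hour).
#' @param drop_packets Integer vector of global 0-based packet indices to
#'   delete from the amplifier and timestamp streams.
#' @param truth Optional `ground_truth` to write alongside.
#' @return The emitted [session_config()], invisibly.
#' @export
write_session <- function(signals, records, spec, out_dir,
                          segment_length_s = 3600, drop_packets = integer(0),
                          truth = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fs <- spec$sample_rate_hz
  P <- spec$samples_per_packet
  n_ch <- nrow(signals)
  config <- session_config(
    num_channels = n_ch,
    animals = lapply(seq_len(spec$n_animals), function(a) {
      animal_channels(sprintf("m%d", a), 2L * (a - 1L), 2L * (a - 1L) + 1L)
    }),
    sample_rate_hz = fs, samples_per_packet = P,
    raw_offset_bits = 32768L,
    nominal_frame_rate_hz = 1000 / spec$frame_period_ms)
  raw <- round(signals / config$scale_uv_per_bit) + config$raw_offset_bits
  if (min(raw) < 0 || max(raw) > 65535) {
    lfp_abort("signal exceeds the representable 16-bit range after quantization",
              "lfpmon_range_error")
  }
  n_packets <- ncol(signals) %/% P
  stopifnot(n_packets == nrow(records))
  keep <- setdiff(seq_len(n_packets) - 1L, drop_packets)
  packets_per_seg <- max(1L, floor(segment_length_s * fs / P))
  seg_of <- keep %/% packets_per_seg
  base_time <- as.POSIXct("2022-01-01 00:00:00", tz = "UTC")
  for (s in unique(seg_of)) {
    label <- format(base_time + s * segment_length_s, "%Y-%m-%dT%H-%M-%S")
    pk <- keep[seg_of == s]
    cols <- as.vector(outer(seq_len(P), pk * P, `+`))
    write_amplifier(raw[, cols, drop = FALSE], config,
                    file.path(out_dir, sprintf("%s_amplifier.bin", label)))
    seg_rec <- records[pk + 1L, , drop = FALSE]
    seg_rec$packet_index <- seq_len(nrow(seg_rec)) - 1L
    attr(seg_rec, "samples_per_packet") <- P
    class(seg_rec) <- c("packet_records", "data.frame")
    write_timestamp_file(seg_rec, config,
                         file.path(out_dir, sprintf("%s_ts.bin", label)))
  }
  write_config(config, file.path(out_dir, "config.json"))
  if (!is.null(truth)) {
    seiz <- if (is.null(truth$seizures)) list() else
      truth$seizures[, setdiff(names(truth$seizures), "channels")]
    jsonlite::write_json(
      list(seizures = seiz,
           artifacts = truth$artifacts,
           interictal_spike_times = truth$interictal_spike_times),
      file.path(out_dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows", null = "null")
  }
  invisible(config)
}
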