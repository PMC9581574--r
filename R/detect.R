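#' Seizure-detector settings
#'
#' Bundles every tunable of the two detectors. Defaults follow the analysis
#' GUI: downsample to 500 Hz, bandpass 3-50 Hz, group peaks firing at >= 3 Hz
#' into bursts, merge bursts within 2.5 s, and (spectral method) average
#' 128-point FFT power over 4-40 Hz. `threshold_n_sd` and `min_duration_s`
#' are deliberately user-set: the threshold is `mean + N x SD` of the
#' detection trace.
#'
#' @param threshold_n_sd N in the `mean + N x SD` threshold.
#' @param min_duration_s Minimum event span (first to last peak) in seconds.
#' @param method `"amplitude"` or `"spectral"`.
#' @param downsample_hz Detection rate after downsampling (Hz).
#' @param band_low_hz,band_high_hz Bandpass corners for the amplitude path (Hz).
#' @param sign_multiplier +1 or -1; flips the trace so negative-going spikes
#'   become positive-going peaks.
#' @param min_burst_freq_hz Minimum firing rate within a burst (Hz); peaks at
#'   most `1/min_burst_freq_hz` apart stay in one burst.
#' @param merge_window_s Bursts closer than this (last peak to next first
#'   peak) are merged.
#' @param spectral_window_n Sliding FFT window length in samples.
#' @param spectral_band_low_hz,spectral_band_high_hz Band over which FFT power
#'   is averaged (Hz, inclusive).
#' @param spectral_prefilter Also bandpass-filter before the FFT? The spectral
#'   path downsamples only, by default.
#' @param antialias Anti-alias the downsampling (see [downsample_trace()]).
#' @return A list of class `detection_settings`.
#' @export
detection_settings <- function(threshold_n_sd,
                               min_duration_s,
                               method = c("amplitude", "spectral"),
                               downsample_hz = 500,
                               band_low_hz = 3,
                               band_high_hz = 50,
                               sign_multiplier = 1,
                               min_burst_freq_hz = 3,
                               merge_window_s = 2.5,
                               spectral_window_n = 128L,
                               spectral_band_low_hz = 4,
                               spectral_band_high_hz = 40,
                               spectral_prefilter = FALSE,
                               antialias = TRUE) {
  method <- match.arg(method)
  if (!is_pos_num(threshold_n_sd)) lfp_abort("threshold_n_sd must be positive", "lfpmon_parameter_error")
  if (!is.numeric(min_duration_s) || min_duration_s < 0) {
    lfp_abort("min_duration_s must be non-negative", "lfpmon_parameter_error")
  }
  if (!sign_multiplier %in% c(-1, 1)) lfp_abort("sign_multiplier must be +1 or -1", "lfpmon_parameter_error")
  if (!(band_low_hz > 0 && band_low_hz < band_high_hz && band_high_hz < downsample_hz / 2)) {
    lfp_abort("need 0 < band_low < band_high < downsample_hz/2", "lfpmon_parameter_error")
  }
  if (!(spectral_band_low_hz >= 0 && spectral_band_low_hz < spectral_band_high_hz &&
        spectral_band_high_hz <= downsample_hz / 2)) {
    lfp_abort("spectral band must lie within [0, downsample_hz/2]", "lfpmon_parameter_error")
  }
  if (!is_count(spectral_window_n) || spectral_window_n < 2) {
    lfp_abort("spectral_window_n must be an integer >= 2", "lfpmon_parameter_error")
  }
  if (!is_pos_num(min_burst_freq_hz)) lfp_abort("min_burst_freq_hz must be positive", "lfpmon_parameter_error")
  if (merge_window_s < 0) lfp_abort("merge_window_s must be non-negative", "lfpmon_parameter_error")
  structure(
    list(method = method, downsample_hz = downsample_hz,
         band_low_hz = band_low_hz, band_high_hz = band_high_hz,
         sign_multiplier = sign_multiplier, threshold_n_sd = threshold_n_sd,
         min_burst_freq_hz = min_burst_freq_hz, merge_window_s = merge_window_s,
         min_duration_s = min_duration_s, spectral_window_n = as.integer(spectral_window_n),
         spectral_band_low_hz = spectral_band_low_hz,
         spectral_band_high_hz = spectral_band_high_hz,
         spectral_prefilter = spectral_prefilter, antialias = antialias),
    class = "detection_settings"
  )
}

#' Save / load detector settings as JSON
#'
#' @param settings A [detection_settings()].
#' @param path JSON path.
#' @return `path` invisibly; `load_detection_settings` returns the settings.
#' @export
save_detection_settings <- function(settings, path) {
  stopifnot(inherits(settings, "detection_settings"))
  jsonlite::write_json(unclass(settings), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_detection_settings
#' @export
load_detection_settings <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(detection_settings, doc)
}

#' Preprocess a trace for detection
#'
#' Downsamples to `settings$downsample_hz`, bandpass filters (zero-phase
#' 4th-order Butterworth between the configured corners) and applies the sign
#' multiplier. This is the detection trace whose mean and SD set the
#' threshold.
#'
#' @param trace Microvolt vector at `sample_rate_hz`.
#' @param settings A [detection_settings()].
#' @param sample_rate_hz Input sampling rate (Hz).
#' @param bandpass Apply the bandpass (the spectral path skips it by default).
#' @return Numeric detection trace at `settings$downsample_hz`.
#' @export
preprocess <- function(trace, settings, sample_rate_hz, bandpass = TRUE) {
  stopifnot(inherits(settings, "detection_settings"))
  x <- downsample_trace(trace, sample_rate_hz, settings$downsample_hz,
                        antialias = settings$antialias)
  if (bandpass) {
    d <- butter_design(2, c(settings$band_low_hz, settings$band_high_hz),
                       settings$downsample_hz, "pass")
    x <- filtfilt(d$b, d$a, x)
  }
  settings$sign_multiplier * x
}

#' Detection threshold: mean + N x SD
#'
#' Computed over the full analyzed trace. A constant trace (SD = 0) returns
#' the mean with a warning.
#'
#' @param detection_trace Numeric vector.
#' @param n_sd N.
#' @return Threshold value on the scale of the trace.
#' @export
compute_threshold <- function(detection_trace, n_sd) {
  if (!length(detection_trace)) lfp_abort("empty detection trace", "lfpmon_parameter_error")
  s <- stats::sd(detection_trace)
  if (is.na(s) || s == 0) {
    lfp_warn("constant detection trace: SD is 0, threshold equals the mean",
             "lfpmon_constant_trace_warning")
    s <- 0
  }
  mean(detection_trace) + n_sd * s
}

#' Find peaks above a threshold
#'
#' A sample is a peak when it is a local maximum strictly above the threshold;
#' plateaus report their first sample. Times are seconds from trace start
#' (sample 1 = time 0).
#'
#' @param detection_trace Numeric vector.
#' @param threshold Threshold on the trace scale.
#' @param rate_hz Sampling rate of the trace (Hz).
#' @return Numeric vector of peak times in seconds.
#' @export
find_peaks_above <- function(detection_trace, threshold, rate_hz) {
  n <- length(detection_trace)
  if (n < 3) return(numeric(0))
  x <- detection_trace
  s <- sign(diff(x))
  nz <- which(s != 0)
  if (length(nz) < 2) return(numeric(0))
  sv <- s[nz]
  # a peak is a rising step whose next non-flat step falls; the peak sample is
  # the one right after the rising step (= first sample of any plateau)
  trans <- which(sv[-length(sv)] == 1 & sv[-1] == -1)
  idx <- nz[trans] + 1L
  idx <- idx[x[idx] > threshold]
  (idx - 1L) / rate_hz
}

#' Group threshold peaks into bursts
#'
#' Consecutive peaks whose inter-peak interval is at most
#' `1/min_burst_freq_hz` (ties inclusive) belong to one burst; a burst may be
#' a single peak.
#'
#' @param peak_times Sorted peak times (s).
#' @param min_burst_freq_hz Minimum within-burst firing rate (Hz).
#' @return List of numeric vectors, one per burst.
#' @export
group_peaks_to_bursts <- function(peak_times, min_burst_freq_hz) {
  if (!length(peak_times)) return(list())
  max_gap <- 1 / min_burst_freq_hz
  tol <- 1e-12 * max(1, max(abs(peak_times)))
  brk <- which(diff(peak_times) > max_gap + tol)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(peak_times))
  mapply(function(s, e) peak_times[s:e], starts, ends, SIMPLIFY = FALSE)
}

#' Merge nearby bursts
#'
#' Consecutive bursts whose gap (next burst's first peak minus this burst's
#' last peak) is at most `merge_window_s` are concatenated; applied until a
#' fixed point (a single left-to-right pass reaches it).
#'
#' @param bursts List of sorted peak-time vectors, in time order.
#' @param merge_window_s Merge window (s), ties inclusive.
#' @return List of merged bursts.
#' @export
merge_bursts <- function(bursts, merge_window_s) {
  if (length(bursts) <= 1L) return(bursts)
  tol <- 1e-12 * max(1, abs(bursts[[length(bursts)]][1]))
  out <- list(bursts[[1]])
  for (b in bursts[-1]) {
    last <- out[[length(out)]]
    if (b[1] - last[length(last)] <= merge_window_s + tol) {
      out[[length(out)]] <- c(last, b)
    } else {
      out[[length(out) + 1L]] <- b
    }
  }
  out
}

new_seizure_events <- function(bursts, channel, method, threshold) {
  onset <- vapply(bursts, function(b) b[1], numeric(1))
  offset <- vapply(bursts, function(b) b[length(b)], numeric(1))
  out <- data.frame(onset_s = onset,
                    offset_s = offset,
                    duration_s = offset - onset,
                    n_peaks = vapply(bursts, length, integer(1)),
                    channel = rep(channel, length(bursts)),
                    method = rep(method, length(bursts)),
                    threshold_used = rep(threshold, length(bursts)))
  out$peak_times_s <- unname(bursts)
  class(out) <- c("seizure_events", "data.frame")
  out
}

empty_seizure_events <- function(channel = NA_integer_, method = NA_character_,
                                 threshold = NA_real_) {
  out <- new_seizure_events(list(), channel[0], method[0], threshold[0])
  out
}

#' Keep bursts long enough to be putative seizures
#'
#' An event's duration is its last peak time minus its first peak time; bursts
#' shorter than `min_duration_s` are dropped. No onset/offset refinement is
#' attempted beyond the peak extremes.
#'
#' @param bursts List of merged bursts.
#' @param min_duration_s Minimum duration (s).
#' @param channel,method,threshold Metadata stamped on the events.
#' @return A `seizure_events` data.frame (columns `onset_s`, `offset_s`,
#'   `duration_s`, `n_peaks`, `channel`, `method`, `threshold_used`, and a
#'   list column `peak_times_s`).
#' @export
filter_by_duration <- function(bursts, min_duration_s, channel = NA_integer_,
                               method = NA_character_, threshold = NA_real_) {
  span <- vapply(bursts, function(b) b[length(b)] - b[1], numeric(1))
  keep <- span >= min_duration_s
  new_seizure_events(bursts[keep], channel, method, threshold)
}

#' Amplitude-threshold seizure detection
#'
#' The first detector: downsample, bandpass 3-50 Hz (zero phase), threshold at
#' `mean + N x SD` of the filtered trace, group supra-threshold peaks firing
#' at >= 3 Hz into bursts, merge bursts within 2.5 s, and keep events at least
#' `min_duration_s` long.
#'
#' @param trace Microvolt vector at `sample_rate_hz`.
#' @param settings A [detection_settings()].
#' @param sample_rate_hz Input sampling rate (Hz).
#' @param channel Channel index stamped on events.
#' @return A `seizure_events` data.frame.
#' @export
detect_amplitude <- function(trace, settings, sample_rate_hz, channel = NA_integer_) {
  x <- preprocess(trace, settings, sample_rate_hz, bandpass = TRUE)
  thr <- compute_threshold(x, settings$threshold_n_sd)
  peaks <- find_peaks_above(x, thr, settings$downsample_hz)
  bursts <- group_peaks_to_bursts(peaks, settings$min_burst_freq_hz)
  bursts <- merge_bursts(bursts, settings$merge_window_s)
  filter_by_duration(bursts, settings$min_duration_s, channel, "amplitude", thr)
}

spectral_band_bins <- function(window_n, band_low, band_high, rate_hz) {
  k <- 0:(window_n - 1)
  freq <- k * rate_hz / window_n
  which(freq >= band_low & freq <= band_high) - 1L   # DFT bin numbers
}

#' Sliding-window FFT band power
#'
#' Applies a length-`spectral_window_n` rectangular-window DFT sliding by one
#' sample and averages `|DFT|^2` over the bins whose centre frequency lies in
#' `[band_low, band_high]` inclusive (at 500 Hz / 128 points this is bins
#' 2-10, 7.8-39.1 Hz). Output element `w` corresponds to the window starting
#' at sample `w`. Implemented as one FFT convolution per band bin, which is
#' numerically identical to the direct per-window DFT.
#'
#' @param detection_trace Numeric vector (already downsampled).
#' @param spectral_window_n Window length in samples.
#' @param band Numeric `c(low, high)` in Hz.
#' @param rate_hz Sampling rate of the trace (Hz).
#' @return Power trace of length `length(trace) - spectral_window_n + 1`.
#' @export
sliding_band_power <- function(detection_trace, spectral_window_n, band, rate_hz) {
  n <- length(detection_trace)
  L <- as.integer(spectral_window_n)
  if (n < L) {
    lfp_abort(sprintf("trace length %d is shorter than the %d-point window", n, L),
              "lfpmon_parameter_error")
  }
  bins <- spectral_band_bins(L, band[1], band[2], rate_hz)
  n_out <- n - L + 1L
  if (!length(bins)) return(rep(0, n_out))
  # overlap-save FFT convolution batched across blocks: each band bin's
  # sliding DFT coefficient is the correlation of the trace with that bin's
  # complex exponential, numerically identical to the direct per-window DFT
  blocks <- os_block_fft(detection_trace, L, n_out)
  acc <- numeric(n_out)
  for (k in bins) {
    h <- exp(-2i * pi * k * (0:(L - 1)) / L)
    y <- os_correlate(blocks, h)
    acc <- acc + Re(y)^2 + Im(y)^2
  }
  acc / length(bins)
}

#' Spectral seizure detection
#'
#' The second detector: downsample (no bandpass by default), compute the
#' sliding 128-point FFT band power averaged over 4-40 Hz, threshold the power
#' trace at `mean + N x SD`, then group, merge and duration-filter peaks
#' exactly as in the amplitude method.
#'
#' @inheritParams detect_amplitude
#' @return A `seizure_events` data.frame.
#' @export
detect_spectral <- function(trace, settings, sample_rate_hz, channel = NA_integer_) {
  x <- preprocess(trace, settings, sample_rate_hz, bandpass = settings$spectral_prefilter)
  pw <- sliding_band_power(x, settings$spectral_window_n,
                           c(settings$spectral_band_low_hz, settings$spectral_band_high_hz),
                           settings$downsample_hz)
  thr <- compute_threshold(pw, settings$threshold_n_sd)
  peaks <- find_peaks_above(pw, thr, settings$downsample_hz)
  bursts <- group_peaks_to_bursts(peaks, settings$min_burst_freq_hz)
  bursts <- merge_bursts(bursts, settings$merge_window_s)
  filter_by_duration(bursts, settings$min_duration_s, channel, "spectral", thr)
}

#' Run the detector selected by `settings$method`
#'
#' @inheritParams detect_amplitude
#' @return A `seizure_events` data.frame.
#' @export
detect_seizures <- function(trace, settings, sample_rate_hz, channel = NA_integer_) {
  if (settings$method == "amplitude") {
    detect_amplitude(trace, settings, sample_rate_hz, channel)
  } else {
    detect_spectral(trace, settings, sample_rate_hz, channel)
  }
}

#' Export events as CSV
#'
#' Columns: `event_id`, `channel`, `method`, `onset_s`, `offset_s`,
#' `duration_s`, `n_peaks`, `threshold_n_sd`, `settings_hash`. The settings
#' hash is a short fingerprint of the serialized settings so result files are
#' traceable to their parameters.
#'
#' @param events A `seizure_events` data.frame.
#' @param settings The [detection_settings()] used.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, settings, path) {
  df <- as.data.frame(events)[, c("channel", "method", "onset_s", "offset_s",
                                  "duration_s", "n_peaks"), drop = FALSE]
  df <- cbind(event_id = seq_len(nrow(df)), df)
  df$threshold_n_sd <- rep(settings$threshold_n_sd, nrow(df))
  df$settings_hash <- rep(settings_hash(settings), nrow(df))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

settings_hash <- function(settings) {
  s <- jsonlite::toJSON(unclass(settings), auto_unbox = TRUE, digits = NA)
  # tiny polynomial rolling hash over the serialized settings (fingerprint
  # only); kept in doubles to stay exact below 2^53
  h <- 5381
  for (byte in utf8ToInt(as.character(s))) h <- (h * 33 + byte) %% 2^31
  sprintf("%08x", as.integer(h))
}
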