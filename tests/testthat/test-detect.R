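# detect: preprocessing, thresholding, peaks, bursts, both detectors

settings_amp <- function(min_duration_s = 3, ...) {
  detection_settings(threshold_n_sd = 5, min_duration_s = min_duration_s, ...)
}

test_that("preprocess attenuates out-of-band frequencies, zero-phase", {
  st <- settings_amp()
  fs <- 2000
  t <- (0:(20 * fs - 1)) / fs
  core <- 2000:7000   # away from edges, at 500 Hz
  g10 <- sd(preprocess(sin(2 * pi * 10 * t), st, fs)[core])
  g100 <- sd(preprocess(sin(2 * pi * 100 * t), st, fs)[core])
  expect_gt(20 * log10(g10 / g100), 20)   # >= 20 dB relative attenuation
  # length contract and linear edge cases
  expect_equal(length(preprocess(t, st, fs)), floor(length(t) * 500 / fs))
  expect_equal(preprocess(numeric(4000), st, fs), numeric(1000))
  x <- rnorm(4000)
  st_neg <- settings_amp(sign_multiplier = -1)
  expect_equal(preprocess(x, st_neg, fs), -preprocess(x, st, fs))
  # zero phase: a bandpassed burst peaks where the input burst peaks
  burst <- numeric(20 * fs)
  burst[10 * fs] <- 1000
  y <- preprocess(burst, st, fs)
  expect_lt(abs(which.max(y) / 500 - 10), 0.02)
  expect_error(preprocess(x, st, 250), class = "lfpmon_parameter_error")
})

test_that("compute_threshold is mean + N * SD with degenerate handling", {
  set.seed(8)
  x <- rnorm(1000)
  x <- (x - mean(x)) / sd(x)           # exactly mean 0, sd 1
  expect_equal(compute_threshold(x, 5), 5)
  expect_warning(thr <- compute_threshold(rep(3, 10), 7),
                 class = "lfpmon_constant_trace_warning")
  expect_equal(thr, 3)
  # homogeneity: scaling by c scales (threshold - mean) by c
  y <- rnorm(500)
  for (c_ in c(0.1, 10)) {
    expect_equal(compute_threshold(c_ * y, 4) - mean(c_ * y),
                 c_ * (compute_threshold(y, 4) - mean(y)))
  }
})

test_that("find_peaks_above finds apexes, plateaus and nothing below threshold", {
  tri <- c(rep(0, 10), seq(0, 10, by = 1), seq(9, 0, by = -1), rep(0, 10))
  expect_equal(find_peaks_above(tri, 5, 1), 20)       # apex index 21, time 20 s
  expect_equal(find_peaks_above(tri, 20, 1), numeric(0))
  # plateau reports its first sample
  plat <- c(0, 1, 5, 5, 5, 1, 0)
  expect_equal(find_peaks_above(plat, 2, 1), 2)
  # comb of 10 pulses at 10 Hz (100 Hz trace): peaks 0.1 s apart
  pulse <- c(0, 5, 10, 5, 0, 0, 0, 0, 0, 0)
  comb <- c(rep(pulse, 10), 0)
  pk <- find_peaks_above(comb, 5, 100)
  expect_length(pk, 10)
  expect_equal(diff(pk), rep(0.1, 9))
})

test_that("burst grouping and merging follow the gap rules", {
  expect_equal(group_peaks_to_bursts(c(0, 0.3, 0.6), 3), list(c(0, 0.3, 0.6)))
  expect_equal(group_peaks_to_bursts(c(0, 0.4), 3), list(0, 0.4))
  expect_equal(group_peaks_to_bursts(numeric(0), 3), list())
  # tie: exactly 1/3 s stays in one burst
  expect_length(group_peaks_to_bursts(c(0, 1 / 3), 3), 1)

  b <- list(c(0, 1), c(3, 4))         # gap 2.0 <= 2.5 -> merge
  expect_equal(merge_bursts(b, 2.5), list(c(0, 1, 3, 4)))
  b2 <- list(c(0, 1), c(4, 5))        # gap 3.0 > 2.5 -> keep
  expect_equal(merge_bursts(b2, 2.5), b2)
  # idempotence at a fixed point
  set.seed(2)
  pk <- sort(runif(40, 0, 60))
  m1 <- merge_bursts(group_peaks_to_bursts(pk, 3), 2.5)
  expect_equal(merge_bursts(m1, 2.5), m1)
})

test_that("grouping + merging agree with a brute-force partitioner", {
  # oracle: O(n^2) scan deciding for every adjacent pair whether the chain
  # stays connected under the two-stage rule
  brute <- function(pk, min_freq, merge_s) {
    if (!length(pk)) return(list())
    bursts <- list(pk[1])
    for (p in pk[-1]) {
      last <- bursts[[length(bursts)]]
      if (p - last[length(last)] <= 1 / min_freq) {
        bursts[[length(bursts)]] <- c(last, p)
      } else bursts[[length(bursts) + 1]] <- p
    }
    merged <- list(bursts[[1]])
    for (b in bursts[-1]) {
      last <- merged[[length(merged)]]
      if (b[1] - last[length(last)] <= merge_s) {
        merged[[length(merged)]] <- c(last, b)
      } else merged[[length(merged) + 1]] <- b
    }
    merged
  }
  set.seed(13)
  grid <- seq(0, 6, by = 0.25)        # includes exact-tie gaps
  for (i in 1:200) {
    n <- sample(0:8, 1)
    pk <- sort(sample(grid, n))
    got <- merge_bursts(group_peaks_to_bursts(pk, 3), 2.5)
    expect_equal(got, brute(pk, 3, 2.5))
  }
})

test_that("filter_by_duration keeps spans >= minimum", {
  bursts <- list(c(0, 2.5, 5), c(10, 11))
  ev <- filter_by_duration(bursts, 3, channel = 2L, method = "amplitude", threshold = 1.5)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset_s, 0)
  expect_equal(ev$offset_s, 5)
  expect_equal(ev$duration_s, 5)
  expect_equal(ev$n_peaks, 3L)
  expect_equal(ev$peak_times_s[[1]], c(0, 2.5, 5))
  ev0 <- filter_by_duration(bursts, 0)
  expect_equal(nrow(ev0), 2L)
  expect_equal(nrow(filter_by_duration(bursts, 10)), 0L)
})

test_that("detect_amplitude recovers an injected spike train", {
  fs <- 2000
  set.seed(21)
  n <- 120 * fs
  x <- rnorm(n)                        # white background, sd 1
  spike_t <- seq(50, 55, by = 0.1)     # 10 Hz train, 5 s
  w <- 15 * sin(pi * seq(0, 1, length.out = 40))   # 15 sd, 20 ms lobes
  for (t0 in spike_t) {
    i <- round(t0 * fs) + seq_along(w)
    x[i] <- x[i] + w
  }
  ev <- detect_amplitude(x, settings_amp(), fs)
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$onset_s - 50), 0.2)
  expect_lt(abs(ev$offset_s - 55), 0.2)
  # zero trace -> constant-trace warning, no events
  expect_warning(ev0 <- detect_amplitude(numeric(8000), settings_amp(), fs),
                 class = "lfpmon_constant_trace_warning")
  expect_equal(nrow(ev0), 0L)
})

test_that("two trains 2 s apart merge into one event", {
  fs <- 2000
  set.seed(22)
  x <- rnorm(60 * fs)
  w <- 15 * sin(pi * seq(0, 1, length.out = 40))
  for (t0 in c(seq(20, 22, by = 0.1), seq(24, 26, by = 0.1))) {
    i <- round(t0 * fs) + seq_along(w)
    x[i] <- x[i] + w
  }
  ev <- detect_amplitude(x, settings_amp(), fs)   # min_duration 3 < merged span 6
  expect_equal(nrow(ev), 1L)
  expect_gte(ev$duration_s, 5.5)
})

test_that("detect_amplitude equals the manual five-stage composition", {
  fs <- 2000
  set.seed(23)
  x <- rnorm(30 * fs) * 10
  x[seq(10 * fs, 12 * fs, by = fs / 5)] <- 300
  st <- settings_amp(min_duration_s = 1)
  d <- preprocess(x, st, fs)
  thr <- compute_threshold(d, st$threshold_n_sd)
  manual <- filter_by_duration(
    merge_bursts(group_peaks_to_bursts(
      find_peaks_above(d, thr, st$downsample_hz), st$min_burst_freq_hz),
      st$merge_window_s),
    st$min_duration_s, NA_integer_, "amplitude", thr)
  expect_events_equal(detect_amplitude(x, st, fs), manual)
})

test_that("sliding_band_power matches a direct DFT and handles DC", {
  set.seed(31)
  x <- rnorm(4000)
  pw <- sliding_band_power(x, 128, c(4, 40), 500)
  expect_length(pw, 4000 - 127)
  direct <- function(w) {
    seg <- x[w:(w + 127)]
    ks <- 2:10   # bins with centre frequency in [4, 40] at 500/128 Hz
    mean(sapply(ks, function(k) Mod(sum(seg * exp(-2i * pi * k * (0:127) / 128)))^2))
  }
  ws <- sample(length(pw), 25)
  expect_lt(max(abs(pw[ws] - sapply(ws, direct)) / pmax(pw[ws], 1e-12)), 1e-9)
  # DC excluded by the 4 Hz lower bound
  expect_equal(sliding_band_power(rep(3, 300), 128, c(4, 40), 500),
               rep(0, 173), tolerance = 1e-20)
  # stationary sine -> approximately constant power away from edges
  t <- (0:2999) / 500
  ps <- sliding_band_power(sin(2 * pi * 10 * t), 128, c(4, 40), 500)
  core <- ps[200:2600]
  expect_lt(max(core) / min(core), 1.3)
  expect_error(sliding_band_power(rnorm(64), 128, c(4, 40), 500),
               class = "lfpmon_parameter_error")
})

test_that("detect_spectral finds the injected seizure and nothing in noise", {
  fs <- 2000
  set.seed(41)
  n <- 300 * fs
  x <- rnorm(n)
  w <- 15 * sin(pi * seq(0, 1, length.out = 40))
  for (t0 in seq(120, 128, by = 0.125)) {
    i <- round(t0 * fs) + seq_along(w)
    x[i] <- x[i] + w
  }
  st <- settings_amp(method = "spectral")
  ev <- detect_spectral(x, st, fs)
  expect_equal(nrow(ev), 1L)
  expect_lt(ev$onset_s, 128); expect_gt(ev$offset_s, 120)  # overlaps injection
  # stationary noise at N = 10: no events across seeds
  st10 <- detection_settings(threshold_n_sd = 10, min_duration_s = 3,
                             method = "spectral")
  for (seed in 1:5) {
    set.seed(seed)
    expect_equal(nrow(detect_spectral(rnorm(30 * fs), st10, fs)), 0L)
  }
})

test_that("both detectors are scale invariant", {
  fs <- 2000
  set.seed(51)
  x <- rnorm(120 * fs)
  w <- 15 * sin(pi * seq(0, 1, length.out = 40))
  for (t0 in seq(40, 46, by = 0.125)) {
    i <- round(t0 * fs) + seq_along(w)
    x[i] <- x[i] + w
  }
  st_a <- settings_amp(); st_s <- settings_amp(method = "spectral")
  ref_a <- detect_amplitude(x, st_a, fs)
  ref_s <- detect_spectral(x, st_s, fs)
  expect_equal(nrow(ref_a), 1L)
  for (c_ in c(0.1, 10)) {
    expect_events_equal(detect_amplitude(c_ * x, st_a, fs), ref_a)
    expect_events_equal(detect_spectral(c_ * x, st_s, fs), ref_s)
  }
})

test_that("raising N or min_duration never adds detections", {
  fs <- 2000
  set.seed(61)
  x <- rnorm(60 * fs)
  w <- 12 * sin(pi * seq(0, 1, length.out = 40))
  for (t0 in c(seq(10, 14, by = 0.2), seq(30, 33, by = 0.15))) {
    i <- round(t0 * fs) + seq_along(w)
    x[i] <- x[i] + w
  }
  d <- preprocess(x, settings_amp(), fs)
  n_peaks <- sapply(c(2, 3, 5, 8), function(N) {
    length(find_peaks_above(d, compute_threshold(d, N), 500))
  })
  expect_true(all(diff(n_peaks) <= 0))
  n_events <- sapply(c(0, 1, 3, 6), function(md) {
    nrow(detect_amplitude(x, detection_settings(threshold_n_sd = 5,
                                                min_duration_s = md), fs))
  })
  expect_true(all(diff(n_events) <= 0))
})

test_that("recovery invariant: seizure-only schedules give exactly K events", {
  # module invariant at reduced scale (5 seeds x 300 s; the full 20 x 1 h world
  # runs in test-acceptance.R)
  for (seed in 1:5) {
    spec <- simulation_spec(
      seed = seed, duration_s = 300, n_animals = 1, interictal_rate_hz = 0,
      seizures = data.frame(animal = 1,
                            start_s = c(60, 150, 240), duration_s = c(8, 7, 9),
                            spike_rate_hz = 8, amplitude_uv = 500,
                            bilateral = FALSE))
    gen <- generate_signals(spec)
    truth <- gen$truth$seizures
    for (method in c("amplitude", "spectral")) {
      ev <- detect_seizures(gen$signals[1, ],
                            settings_amp(method = method), 2000, channel = 0)
      expect_equal(nrow(ev), 3L, info = paste(method, "seed", seed))
      m <- match_to_ground_truth(ev, truth)
      expect_equal(m$false_neg, 0L, info = paste(method, "seed", seed))
      expect_equal(m$false_pos, 0L, info = paste(method, "seed", seed))
    }
  }
})

test_that("settings save/load roundtrip and validation", {
  st <- detection_settings(threshold_n_sd = 4.5, min_duration_s = 2,
                           method = "spectral", sign_multiplier = -1)
  p <- tempfile(fileext = ".json")
  save_detection_settings(st, p)
  expect_equal(load_detection_settings(p), st)
  expect_error(detection_settings(threshold_n_sd = 5, min_duration_s = 1,
                                  band_low_hz = 60, band_high_hz = 50),
               class = "lfpmon_parameter_error")
  expect_error(detection_settings(threshold_n_sd = 5, min_duration_s = 1,
                                  band_high_hz = 400),
               class = "lfpmon_parameter_error")
  expect_error(detection_settings(threshold_n_sd = -1, min_duration_s = 1),
               class = "lfpmon_parameter_error")
})
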