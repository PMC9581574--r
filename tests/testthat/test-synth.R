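# synth: generative model, frame assignment, session writing

test_that("zero noise + one seizure leaves exactly the spike train", {
  spec <- simulation_spec(seed = 1, duration_s = 20, n_animals = 1,
                          noise_sd_uv = 0, interictal_rate_hz = 0,
                          seizures = data.frame(animal = 1, start_s = 5,
                                                duration_s = 4, spike_rate_hz = 5,
                                                amplitude_uv = 200, bilateral = FALSE))
  gen <- generate_signals(spec)
  x <- gen$signals[1, ]
  expect_true(all(gen$signals[2, ] == 0))         # unilateral
  expect_true(all(x[1:9999] == 0))                # quiet before onset
  # waveform grid does not sample the sine apex exactly; peak within 1%
  expect_equal(max(x), 200, tolerance = 0.01)
  # one local maximum per spike, at the scheduled 5 Hz spacing
  pk <- find_peaks_above(x, 100, 2000)
  expect_length(pk, 21)
  expect_equal(diff(pk), rep(0.2, 20))
  expect_equal(gen$truth$seizures$start_s, 5)
})

test_that("generation is deterministic in the seed", {
  spec <- simulation_spec(seed = 33, duration_s = 10, n_animals = 2)
  g1 <- generate_signals(spec)
  g2 <- generate_signals(spec)
  expect_identical(g1$signals, g2$signals)
  expect_identical(g1$truth$interictal_spike_times, g2$truth$interictal_spike_times)
  g3 <- generate_signals(simulation_spec(seed = 34, duration_s = 10, n_animals = 2))
  expect_false(identical(g1$signals, g3$signals))
})

test_that("cross-animal channels are independent, within-animal mixing works", {
  spec <- simulation_spec(seed = 44, duration_s = 60, n_animals = 2,
                          interictal_rate_hz = 0, shared_source_mixing = 0)
  sig <- generate_signals(spec)$signals
  n <- ncol(sig)
  # effective sample count of 1/f noise is below n; use a generous CLT bound
  expect_lt(abs(cor(sig[1, ], sig[3, ])), 0.1)
  expect_lt(abs(cor(sig[2, ], sig[4, ])), 0.1)
  expect_lt(abs(cor(sig[1, ], sig[2, ])), 0.1)    # mixing 0 -> L/R independent too
  spec2 <- simulation_spec(seed = 44, duration_s = 60, n_animals = 1,
                           interictal_rate_hz = 0, shared_source_mixing = 0.5)
  sig2 <- generate_signals(spec2)$signals
  expect_gt(cor(sig2[1, ], sig2[2, ]), 0.3)       # shared source
})

test_that("schedule validation rejects bad specs", {
  expect_error(simulation_spec(duration_s = 10,
                               seizures = data.frame(animal = 1, start_s = 8,
                                                     duration_s = 5, spike_rate_hz = 5,
                                                     amplitude_uv = 100, bilateral = FALSE)),
               class = "lfpmon_spec_error")
  expect_error(simulation_spec(duration_s = 60,
                               seizures = data.frame(animal = 1, start_s = c(5, 8),
                                                     duration_s = 10, spike_rate_hz = 5,
                                                     amplitude_uv = 100, bilateral = FALSE)),
               class = "lfpmon_spec_error")
  expect_error(simulation_spec(shared_source_mixing = 1.5), class = "lfpmon_spec_error")
})

test_that("frame assignment matches a brute-force event merge", {
  # equal frame and packet periods: consecutive distinct frames, zero gaps
  spec_eq <- simulation_spec(seed = 5, duration_s = 30, frame_period_ms = 128,
                             sample_rate_hz = 2000, samples_per_packet = 256L)
  rec <- simulate_frame_assignment(spec_eq)
  expect_true(all(diff(rec$frame_index) == 1))
  expect_equal(gap_statistics(build_sync_map(rec))$mean, 0)

  # 30 Hz camera vs 128 ms packets: mean gap from explicit enumeration
  spec30 <- simulation_spec(seed = 6, duration_s = 120, frame_period_ms = 1000 / 30)
  rec30 <- simulate_frame_assignment(spec30)
  brute <- function(spec) {
    fs <- spec$sample_rate_hz; P <- spec$samples_per_packet
    n_pk <- floor(spec$duration_s * fs) %/% P
    arrival <- (seq_len(n_pk) * P / fs) * 1000 + spec$packet_emit_latency_ms
    frames <- integer(n_pk)
    for (k in seq_len(n_pk)) {   # most recent frame at or before arrival
      # epsilon guards exact frame/packet coincidences against float rounding
      frames[k] <- floor(arrival[k] / spec$frame_period_ms + 1e-9) + 1
    }
    frames
  }
  expect_equal(rec30$frame_index, brute(spec30))
  gs <- gap_statistics(build_sync_map(rec30))
  expect_equal(gs$mean, 128 / (1000 / 30) - 1, tolerance = 0.01)

  # halving the packet period never increases the mean gap
  means <- sapply(c(500, 1000, 2000, 4000), function(fs) {
    sp <- simulation_spec(seed = 7, duration_s = 60, sample_rate_hz = fs)
    gap_statistics(build_sync_map(simulate_frame_assignment(sp)))$mean
  })
  expect_true(all(diff(means) <= 1e-9))
})

test_that("jittered frames still yield non-decreasing assignments", {
  spec <- simulation_spec(seed = 8, duration_s = 60, frame_latency_jitter_ms = 10)
  rec <- simulate_frame_assignment(spec)
  expect_true(all(diff(rec$frame_index) >= 0))
  expect_silent(build_sync_map(rec))
})

test_that("written sessions round-trip within half a bit", {
  spec <- simulation_spec(seed = 9, duration_s = 30, n_animals = 2)
  gen <- generate_signals(spec)
  rec <- simulate_frame_assignment(spec)
  dir <- tempfile()
  write_session(gen$signals, rec, spec, dir, segment_length_s = 15,
                truth = gen$truth)
  man <- discover_session(dir)
  expect_equal(nrow(man), 2L)   # two segments, both streams present
  cfg <- parse_config(file.path(dir, "config.json"))
  expect_equal(cfg$raw_offset_bits, 32768L)
  back <- do.call(cbind, lapply(man$amplifier_path, function(p) {
    scale_to_microvolts(read_amplifier(p, cfg), cfg)
  }))
  expect_lt(max(abs(back - gen$signals)), 0.5 * cfg$scale_uv_per_bit + 1e-12)
  # ground truth sidecar exists and matches the schedule
  gt <- jsonlite::fromJSON(file.path(dir, "ground_truth.json"))
  expect_length(gt$interictal_spike_times, 4)
})

test_that("continuity checker finds exactly the injected gaps", {
  set.seed(10)
  for (i in 1:5) {
    spec <- simulation_spec(seed = 10 + i, duration_s = 20, n_animals = 1)
    gen <- generate_signals(spec)
    rec <- simulate_frame_assignment(spec)
    n_pk <- nrow(rec)
    # random non-adjacent interior packets so gap sizes stay 1 packet each
    cand <- seq(2L, n_pk - 2L, by = 2L)
    drop <- sort(sample(cand, sample(1:3, 1)))
    dir <- tempfile()
    write_session(gen$signals, rec, spec, dir, segment_length_s = 10,
                  drop_packets = drop)
    cfg <- parse_config(file.path(dir, "config.json"))
    man <- discover_session(dir)
    recs <- lapply(man$timestamp_path, read_timestamp_file, config = cfg)
    rep <- check_continuity(recs, man$segment_label)
    expect_equal(rep$n_gaps, length(drop))
    expect_equal(rep$gaps$missing_samples, rep(256, length(drop)))
    expect_equal(rep$total_missing_samples, 256 * length(drop))
  }
})

test_that("single dropped packet loses exactly one packet of samples", {
  dir <- make_session_dir(seed = 12, duration_s = 20, segment_length_s = 20,
                          drop_packets = 40L)
  cfg <- parse_config(file.path(dir, "config.json"))
  man <- discover_session(dir)
  rep <- check_continuity(lapply(man$timestamp_path, read_timestamp_file,
                                 config = cfg))
  expect_equal(rep$n_gaps, 1L)
  expect_equal(rep$gaps$missing_samples, 256)
  expect_equal(rep$gaps$missing_packets, 1)
})

test_that("written-then-read sessions keep detector recovery end to end", {
  for (seed in 1:3) {
    # ictal fraction kept ~5%: the spectral threshold is relative to the
    # analysed trace and saturates on seizure-dominated snippets
    seiz <- data.frame(animal = 1, start_s = c(80, 200), duration_s = c(8, 7),
                       spike_rate_hz = 8, amplitude_uv = 500, bilateral = TRUE)
    spec <- simulation_spec(seed = seed, duration_s = 300, n_animals = 1,
                            seizures = seiz)
    gen <- generate_signals(spec)
    rec <- simulate_frame_assignment(spec)
    dir <- tempfile()
    write_session(gen$signals, rec, spec, dir, segment_length_s = 300,
                  truth = gen$truth)
    cfg <- parse_config(file.path(dir, "config.json"))
    man <- discover_session(dir)
    x <- scale_to_microvolts(read_amplifier(man$amplifier_path[1], cfg), cfg)[1, ]
    for (method in c("amplitude", "spectral")) {
      st <- detection_settings(threshold_n_sd = 5, min_duration_s = 3,
                               method = method)
      ev <- detect_seizures(x, st, cfg$sample_rate_hz)
      m <- match_to_ground_truth(ev, gen$truth$seizures)
      expect_equal(m$false_neg, 0L, info = paste(method, seed))
      expect_equal(m$true_pos, 2L, info = paste(method, seed))
    }
  }
})
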