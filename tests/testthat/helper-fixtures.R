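# Shared fixture builders. Everything is generated in code at test time.

default_config <- function(num_channels = 2, n_animals = num_channels %/% 2, ...) {
  animals <- lapply(seq_len(n_animals), function(a) {
    animal_channels(sprintf("m%d", a), 2L * (a - 1L), 2L * (a - 1L) + 1L)
  })
  session_config(num_channels = num_channels, animals = animals, ...)
}

# random raw amplifier block of whole packets
random_block <- function(config, n_packets, seed = 1) {
  set.seed(seed)
  matrix(sample(0:65535, config$num_channels * n_packets * config$samples_per_packet,
                replace = TRUE),
         nrow = config$num_channels)
}

# packet records with given frame indices and contiguous timestamps
records_from_frames <- function(frames, P = 256L, first_ts = 0) {
  lfpmon:::new_packet_records(seq_along(frames) - 1L,
                              first_ts + (seq_along(frames) - 1L) * P,
                              frames, P)
}

write_config_json <- function(doc, path = tempfile(fileext = ".json")) {
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  path
}

# a tiny written session with optional seizures/gaps; returns its directory
make_session_dir <- function(seed = 1, duration_s = 30, n_animals = 1,
                             segment_length_s = 15, seizures = NULL,
                             drop_packets = integer(0), ...) {
  spec <- simulation_spec(seed = seed, duration_s = duration_s,
                          n_animals = n_animals, seizures = seizures, ...)
  gen <- generate_signals(spec)
  rec <- simulate_frame_assignment(spec)
  dir <- tempfile("session")
  write_session(gen$signals, rec, spec, dir, segment_length_s = segment_length_s,
                drop_packets = drop_packets, truth = gen$truth)
  dir
}

expect_events_equal <- function(a, b) {
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$onset_s, b$onset_s)
  expect_equal(a$offset_s, b$offset_s)
  expect_equal(a$n_peaks, b$n_peaks)
}
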