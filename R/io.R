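#' Read a binary amplifier file
#'
#' Amplifier files hold 16-bit unsigned little-endian raw values as one long
#' vector. The default dialect is packet-blocked and channel-major: the file is
#' a sequence of acquisition packets, and within each packet channel 0's
#' `samples_per_packet` values come first, then channel 1's, and so on
#' (matching the shape of the acquisition buffer). Set
#' `config$layout = "sample_interleaved"` for a channel-fastest interleave.
#'
#' @param path Amplifier file path.
#' @param config A [session_config()].
#' @return A matrix `[num_channels x num_samples]` of raw integer values with
#'   attribute `first_packet_index` (0).
#' @export
read_amplifier <- function(path, config) {
  stopifnot(inherits(config, "session_config"))
  v <- read_uint16(path)
  nch <- config$num_channels
  P <- config$samples_per_packet
  stride <- nch * P
  if (length(v) %% stride != 0L) {
    lfp_abort(sprintf(
      "truncated amplifier file %s: %d bytes leave a residue of %d bytes (packet stride is %d bytes)",
      path, length(v) * 2L, (length(v) %% stride) * 2L, stride * 2L),
      "lfpmon_format_error")
  }
  n_packets <- length(v) %/% stride
  if (n_packets == 0L) {
    m <- matrix(integer(0), nrow = nch, ncol = 0)
  } else if (config$layout == "packet_blocked") {
    # packet-blocked: dims (sample, channel, packet) in storage order
    a <- array(v, dim = c(P, nch, n_packets))
    m <- matrix(aperm(a, c(2, 1, 3)), nrow = nch)
  } else {
    m <- matrix(v, nrow = nch)
  }
  attr(m, "first_packet_index") <- 0L
  m
}

#' Write a binary amplifier file
#'
#' Inverse of [read_amplifier()]: serializes a raw `[channels x samples]`
#' matrix in the dialect selected by `config$layout`. Values must lie in the
#' 16-bit unsigned range and the sample count must be a whole number of
#' packets.
#'
#' @param block Integer matrix `[num_channels x num_samples]`.
#' @param config A [session_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_amplifier <- function(block, config, path) {
  stopifnot(inherits(config, "session_config"), is.matrix(block))
  nch <- config$num_channels
  P <- config$samples_per_packet
  if (nrow(block) != nch) {
    lfp_abort(sprintf("block has %d rows but config declares %d channels", nrow(block), nch),
              "lfpmon_validation_error")
  }
  if (ncol(block) %% P != 0L) {
    lfp_abort(sprintf("sample count %d is not a multiple of samples_per_packet (%d)",
                      ncol(block), P), "lfpmon_validation_error")
  }
  if (length(block) && (min(block) < 0 || max(block) > 65535)) {
    lfp_abort("raw values outside the 16-bit unsigned range [0, 65535]", "lfpmon_range_error")
  }
  n_packets <- ncol(block) %/% P
  if (n_packets == 0L) {
    v <- integer(0)
  } else if (config$layout == "packet_blocked") {
    a <- array(block, dim = c(nch, P, n_packets))
    v <- as.vector(aperm(a, c(2, 1, 3)))
  } else {
    v <- as.vector(block)
  }
  write_uint16(v, path)
}

#' Convert raw amplifier values to microvolts
#'
#' `uV = (raw - raw_offset_bits) * scale_uv_per_bit`, elementwise. With the
#' default offset of 0 this is the plain 0.195 uV/bit multiplication.
#'
#' @param raw Raw value matrix or vector (16-bit range).
#' @param config A [session_config()].
#' @return Numeric matrix/vector of microvolt values.
#' @export
scale_to_microvolts <- function(raw, config) {
  stopifnot(inherits(config, "session_config"))
  if (length(raw) && (min(raw) < 0 || max(raw) > 65535)) {
    lfp_abort("raw values outside the 16-bit unsigned range", "lfpmon_range_error")
  }
  (raw - config$raw_offset_bits) * config$scale_uv_per_bit
}

# Filename pattern: <label>_<suffix>.<ext>; label must sort chronologically
# (the writers emit ISO-8601-like labels). The label regex is permissive on
# purpose -- only the suffix is fixed by the acquisition workflow.
session_file_regex <- "^(.+)_(amplifier|ts|vid)\\.[A-Za-z0-9]+$"

#' Discover and order the hour-long segments of a session directory
#'
#' Matches files named `<label>_<suffix>.<ext>` with suffix `amplifier`, `ts`
#' or `vid`, pairs them by label, and returns them sorted by label. Every
#' segment must have both an amplifier and a timestamp file; video is
#' optional.
#'
#' @param directory Session directory.
#' @param config A [session_config()] (unused for matching; kept for interface
#'   symmetry with the other readers).
#' @return A data.frame of class `session_manifest` with columns
#'   `segment_label`, `amplifier_path`, `timestamp_path`, `video_path`
#'   (`NA` when absent), one row per segment in chronological order.
#' @export
discover_session <- function(directory, config = NULL) {
  if (!dir.exists(directory)) {
    lfp_abort(sprintf("session directory not found: %s", directory), "lfpmon_manifest_error")
  }
  files <- sort(list.files(directory))
  hit <- grepl(session_file_regex, files)
  files <- files[hit]
  label <- sub(session_file_regex, "\\1", files)
  suffix <- sub(session_file_regex, "\\2", files)
  labels <- sort(unique(label))
  amp <- ts <- vid <- rep(NA_character_, length(labels))
  for (i in seq_along(labels)) {
    sel <- label == labels[i]
    for (j in which(sel)) {
      full <- file.path(directory, files[j])
      switch(suffix[j],
             amplifier = amp[i] <- full,
             ts = ts[i] <- full,
             vid = vid[i] <- full)
    }
  }
  orphans <- labels[is.na(amp) | is.na(ts)]
  if (length(orphans)) {
    lfp_abort(sprintf("segment(s) missing amplifier or timestamp file: %s",
                      paste(orphans, collapse = ", ")),
              "lfpmon_manifest_error")
  }
  out <- data.frame(segment_label = labels,
                    amplifier_path = amp,
                    timestamp_path = ts,
                    video_path = vid,
                    stringsAsFactors = FALSE)
  class(out) <- c("session_manifest", "data.frame")
  out
}
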