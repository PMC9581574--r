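# Packet <-> video-frame synchronization.
#
# Each acquisition packet pairs samples_per_packet consecutive board
# timestamps with the index of the most recently acquired video frame. Packet
# records are stored compactly (first timestamp per packet) because the
# reader enforces the +1-per-sample invariant; everything downstream is
# vectorized over the record table. Packets and frames are 0-based in these
# structures; report helpers use 1-based numbering.

new_packet_records <- function(packet_index, first_ts, frame_index, samples_per_packet) {
  out <- data.frame(packet_index = as.integer(packet_index),
                    first_ts = as.double(first_ts),
                    frame_index = as.double(frame_index))
  attr(out, "samples_per_packet") <- as.integer(samples_per_packet)
  class(out) <- c("packet_records", "data.frame")
  out
}

#' Read a binary timestamp file
#'
#' Timestamp files are 32-bit unsigned little-endian. In the default
#' `"blocked"` dialect each packet record is `samples_per_packet` sample
#' timestamps followed by `samples_per_packet` repeats of the assigned video
#' frame index (the concatenation of the two matching vectors built by the
#' acquisition workflow); `"interleaved"` alternates timestamp/frame pairs.
#' Sample timestamps must increase by exactly 1 within a packet and the frame
#' block must be constant.
#'
#' @param path Timestamp file path.
#' @param config A [session_config()].
#' @return A `packet_records` data.frame with columns `packet_index`
#'   (0-based), `first_ts`, `frame_index`.
#' @export
read_timestamp_file <- function(path, config) {
  stopifnot(inherits(config, "session_config"))
  P <- config$samples_per_packet
  v <- read_uint32(path)
  rec_len <- 2L * P
  if (length(v) %% rec_len != 0L) {
    lfp_abort(sprintf(
      "truncated timestamp file %s: %d values leave a residue of %d (record length %d)",
      path, length(v), length(v) %% rec_len, rec_len), "lfpmon_format_error")
  }
  n_packets <- length(v) %/% rec_len
  if (n_packets == 0L) return(new_packet_records(integer(0), double(0), double(0), P))
  m <- matrix(v, nrow = rec_len)
  if (config$ts_layout == "blocked") {
    ts <- m[seq_len(P), , drop = FALSE]
    fr <- m[P + seq_len(P), , drop = FALSE]
  } else {
    ts <- m[seq.int(1L, rec_len, by = 2L), , drop = FALSE]
    fr <- m[seq.int(2L, rec_len, by = 2L), , drop = FALSE]
  }
  if (P > 1L) {
    dts <- ts[-1L, , drop = FALSE] - ts[-P, , drop = FALSE]
    bad <- which(colSums(dts != 1) > 0)
    if (length(bad)) {
      lfp_abort(sprintf("packet %d: sample timestamps do not increase by 1", bad[1] - 1L),
                "lfpmon_format_error")
    }
    badf <- which(colSums(fr != rep(fr[1L, ], each = P)) > 0)
    if (length(badf)) {
      lfp_abort(sprintf("packet %d: frame block holds more than one frame index", badf[1] - 1L),
                "lfpmon_format_error")
    }
  }
  new_packet_records(seq_len(n_packets) - 1L, ts[1L, ], fr[1L, ], P)
}

#' Write a binary timestamp file
#'
#' Inverse of [read_timestamp_file()]; expands each record back to the
#' two-vector-per-packet binary layout selected by `config$ts_layout`.
#'
#' @param records A `packet_records` data.frame.
#' @param config A [session_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timestamp_file <- function(records, config, path) {
  stopifnot(inherits(config, "session_config"))
  P <- config$samples_per_packet
  n <- nrow(records)
  if (n == 0L) {
    return(write_uint32(double(0), path))
  }
  ts <- outer(0:(P - 1L), records$first_ts, `+`)
  fr <- matrix(rep(records$frame_index, each = P), nrow = P)
  if (config$ts_layout == "blocked") {
    m <- rbind(ts, fr)
  } else {
    m <- matrix(0, nrow = 2L * P, ncol = n)
    m[seq.int(1L, 2L * P, by = 2L), ] <- ts
    m[seq.int(2L, 2L * P, by = 2L), ] <- fr
  }
  write_uint32(as.vector(m), path)
}

#' Build the packet-to-frame synchronization map
#'
#' Validates that frame indices never decrease across packets and extracts the
#' anchors: for each distinct frame index, the sample position (0-based, packet
#' position times `samples_per_packet`) of the first packet that carries it.
#'
#' @param records A `packet_records` data.frame from [read_timestamp_file()].
#' @return A list of class `sync_map` with `records`, `anchors` (data.frame
#'   `frame_index`, `anchor_sample`) and `samples_per_packet`.
#' @export
build_sync_map <- function(records) {
  if (!nrow(records)) lfp_abort("no packet records", "lfpmon_sync_error")
  P <- attr(records, "samples_per_packet")
  fr <- records$frame_index
  dec <- which(diff(fr) < 0)
  if (length(dec)) {
    lfp_abort(sprintf("frame index decreases at packet %d (%g -> %g): clock anomaly",
                      dec[1], fr[dec[1]], fr[dec[1] + 1]), "lfpmon_sync_error")
  }
  first <- !duplicated(fr)
  anchors <- data.frame(frame_index = fr[first],
                        anchor_sample = (which(first) - 1L) * P)
  structure(list(records = records, anchors = anchors, samples_per_packet = P),
            class = "sync_map")
}

#' Interpolate unassigned video frames onto the sample axis
#'
#' The live assignment only anchors the frames present when a packet arrived;
#' frames acquired in between are placed offline by linear interpolation
#' between the neighbouring anchors. Frames outside the anchored range are
#' extrapolated from the nearest anchor pair. Fractional sample positions are
#' kept (`rounding = "none"`); `"nearest"` rounds half-down so ties go to the
#' earlier sample.
#'
#' @param map A `sync_map` from [build_sync_map()].
#' @param rounding `"none"` or `"nearest"`.
#' @return A data.frame of class `frame_timeline` with columns `frame_index`,
#'   `sample_pos`, `assigned` (TRUE for anchor frames). Attribute
#'   `single_anchor` flags the degenerate one-anchor case.
#' @export
interpolate_frames <- function(map, rounding = c("none", "nearest")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(map, "sync_map"))
  a <- map$anchors
  single <- nrow(a) < 2L
  if (single) {
    lfp_warn("sync map has a single anchor; nothing to interpolate", "lfpmon_sync_warning")
    out <- data.frame(frame_index = a$frame_index, sample_pos = as.double(a$anchor_sample),
                      assigned = TRUE)
  } else {
    frames <- seq.int(a$frame_index[1], a$frame_index[nrow(a)])
    # approx is linear between anchors; extrapolation beyond the ends reuses
    # the slope of the nearest anchor pair.
    pos <- stats::approx(a$frame_index, a$anchor_sample, xout = frames)$y
    out <- data.frame(frame_index = frames, sample_pos = pos,
                      assigned = frames %in% a$frame_index)
  }
  if (rounding == "nearest") out$sample_pos <- ceiling(out$sample_pos - 0.5)
  class(out) <- c("frame_timeline", "data.frame")
  attr(out, "single_anchor") <- single
  out
}

#' Extrapolated frame position helper
#'
#' Sample position for an arbitrary frame index, linear between anchors and
#' extrapolated from the nearest anchor pair outside the anchored range.
#'
#' @param map A `sync_map`.
#' @param frame Frame index (vectorized).
#' @return Fractional sample positions.
#' @export
frame_sample_position <- function(map, frame) {
  a <- map$anchors
  if (nrow(a) < 2L) return(rep(as.double(a$anchor_sample[1]), length(frame)))
  f <- a$frame_index; s <- a$anchor_sample
  out <- stats::approx(f, s, xout = frame)$y
  lo <- frame < f[1]
  hi <- frame > f[length(f)]
  if (any(lo)) {
    sl <- (s[2] - s[1]) / (f[2] - f[1])
    out[lo] <- s[1] + (frame[lo] - f[1]) * sl
  }
  if (any(hi)) {
    m <- length(f)
    sl <- (s[m] - s[m - 1]) / (f[m] - f[m - 1])
    out[hi] <- s[m] + (frame[hi] - f[m]) * sl
  }
  out
}

#' Synchronization gap statistics
#'
#' For consecutive anchored frames `f_a < f_b` the gap is `f_b - f_a - 1`, the
#' number of video frames that were never assigned to a voltage packet.
#'
#' @param map A `sync_map`.
#' @return List with `gaps` (integer vector), `n_gaps`, `mean`, `max`.
#' @export
gap_statistics <- function(map) {
  stopifnot(inherits(map, "sync_map"))
  f <- map$anchors$frame_index
  gaps <- if (length(f) >= 2) diff(f) - 1 else numeric(0)
  list(gaps = gaps,
       n_gaps = length(gaps),
       mean = if (length(gaps)) mean(gaps) else NA_real_,
       max = if (length(gaps)) max(gaps) else NA_real_)
}

#' Check sample continuity within and across segments
#'
#' Board timestamps must advance by exactly 1 per sample, so the first
#' timestamp of each packet must equal the previous packet's last timestamp
#' plus one -- within a segment and across the boundary between consecutive
#' hour-long segments. Every violation is reported with its location and the
#' number of missing samples (and whole packets where divisible).
#'
#' @param segments List of `packet_records` in manifest order.
#' @param labels Optional segment labels (defaults to positions).
#' @return A list of class `continuity_report`: `gaps` data.frame (`segment`,
#'   `packet_index`, `expected`, `observed`, `missing_samples`,
#'   `missing_packets`), `total_missing_samples`, `n_gaps`.
#' @export
check_continuity <- function(segments, labels = NULL) {
  if (inherits(segments, "packet_records")) segments <- list(segments)
  if (is.null(labels)) labels <- as.character(seq_along(segments))
  P <- attr(segments[[1]], "samples_per_packet")
  gap_rows <- list()
  prev_end <- NULL   # last timestamp of the previous packet seen
  for (si in seq_along(segments)) {
    rec <- segments[[si]]
    if (!nrow(rec)) next
    first <- rec$first_ts
    exp_first <- c(if (is.null(prev_end)) first[1] else prev_end + 1,
                   first[-length(first)] + P)
    bad <- which(first != exp_first)
    for (b in bad) {
      miss <- first[b] - exp_first[b]
      gap_rows[[length(gap_rows) + 1L]] <- data.frame(
        segment = labels[si],
        packet_index = rec$packet_index[b],
        expected = exp_first[b],
        observed = first[b],
        missing_samples = miss,
        missing_packets = if (miss %% P == 0) miss %/% P else NA_real_)
    }
    prev_end <- first[length(first)] + P - 1
  }
  gaps <- if (length(gap_rows)) do.call(rbind, gap_rows) else
    data.frame(segment = character(0), packet_index = integer(0),
               expected = double(0), observed = double(0),
               missing_samples = double(0), missing_packets = double(0))
  structure(list(gaps = gaps,
                 total_missing_samples = sum(gaps$missing_samples),
                 n_gaps = nrow(gaps)),
            class = "continuity_report")
}

#' @export
print.continuity_report <- function(x, ...) {
  cat(sprintf("<continuity_report> %d gap(s), %g missing sample(s)\n",
              x$n_gaps, x$total_missing_samples))
  if (x$n_gaps) print.data.frame(x$gaps)
  invisible(x)
}

#' Sample and time range of a packet (1-based, report convention)
#'
#' Packet `k` covers samples `(k-1)*P + 1 .. k*P` (1-based) and, at sampling
#' rate `rate`, milliseconds `ceiling(sample * 1000 / rate)` at each end — the
#' numbering used in session reports (packet 5 at 2 kHz with 256-sample
#' packets spans samples 1025–1280, ms 513–640).
#'
#' @param packet_number 1-based packet number.
#' @param config A [session_config()].
#' @return List `first_sample`, `last_sample`, `first_ms`, `last_ms`.
#' @export
packet_sample_range <- function(packet_number, config) {
  stopifnot(inherits(config, "session_config"))
  if (!is_count(packet_number) || packet_number < 1) {
    lfp_abort("packet_number must be a positive integer", "lfpmon_range_error")
  }
  P <- config$samples_per_packet
  first <- (packet_number - 1) * P + 1
  last <- packet_number * P
  per_ms <- config$sample_rate_hz / 1000
  list(first_sample = first,
       last_sample = last,
       first_ms = ceiling(first / per_ms),
       last_ms = ceiling(last / per_ms))
}

#' Export a continuity report as CSV
#'
#' @param report A `continuity_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_continuity_csv <- function(report, path) {
  utils::write.csv(report$gaps, path, row.names = FALSE)
  invisible(path)
}
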