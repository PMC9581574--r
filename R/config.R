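#' Describe one animal's electrode channels
#'
#' Each animal carries a bilateral depth-electrode pair; the two channels index
#' rows of the amplifier matrix (0-based, matching the acquisition software).
#'
#' @param animal_id Short identifier, e.g. `"m1"`.
#' @param left_channel,right_channel 0-based channel indices; must differ.
#' @return A list of class `animal_channels`.
#' @export
animal_channels <- function(animal_id, left_channel, right_channel) {
  if (!is.character(animal_id) || length(animal_id) != 1L || !nzchar(animal_id)) {
    lfp_abort("animal_id must be a non-empty string", "lfpmon_validation_error")
  }
  if (!is_count(left_channel) || !is_count(right_channel)) {
    lfp_abort("channel indices must be non-negative integers", "lfpmon_validation_error")
  }
  if (left_channel == right_channel) {
    lfp_abort(sprintf("animal '%s': left_channel equals right_channel (%d)",
                      animal_id, as.integer(left_channel)),
              "lfpmon_validation_error")
  }
  structure(
    list(animal_id = animal_id,
         left_channel = as.integer(left_channel),
         right_channel = as.integer(right_channel)),
    class = "animal_channels"
  )
}

#' Session configuration
#'
#' Acquisition constants and the animal-to-channel map for one recording
#' session. Defaults mirror the rig: 2 kHz sampling, 256-sample acquisition
#' packets, 0.195 uV per raw bit, a nominally 30 Hz camera.
#'
#' @param num_channels Number of recorded amplifier channels.
#' @param animals List of [animal_channels()] entries (may be empty).
#' @param sample_rate_hz LFP sampling rate in Hz.
#' @param samples_per_packet Voltage samples buffered per acquisition packet.
#' @param scale_uv_per_bit Microvolts per raw 16-bit unit.
#' @param raw_offset_bits Raw units subtracted before scaling (0 keeps the
#'   literal multiply-by-scale conversion; 32768 centres the unsigned range).
#' @param nominal_frame_rate_hz Nominal camera frame rate in Hz.
#' @param layout Amplifier serialization dialect: `"packet_blocked"` (each
#'   packet holds each channel's samples contiguously, channel 0 first) or
#'   `"sample_interleaved"` (channel-fastest interleave).
#' @param ts_layout Timestamp serialization dialect: `"blocked"` (per packet,
#'   all sample timestamps then the repeated frame index) or `"interleaved"`.
#' @return A list of class `session_config`.
#' @export
session_config <- function(num_channels,
                           animals = list(),
                           sample_rate_hz = 2000,
                           samples_per_packet = 256L,
                           scale_uv_per_bit = 0.195,
                           raw_offset_bits = 0L,
                           nominal_frame_rate_hz = 30,
                           layout = c("packet_blocked", "sample_interleaved"),
                           ts_layout = c("blocked", "interleaved")) {
  layout <- match.arg(layout)
  ts_layout <- match.arg(ts_layout)
  if (!is_count(num_channels) || num_channels < 1) {
    lfp_abort("num_channels must be a positive integer", "lfpmon_validation_error")
  }
  if (!is_pos_num(sample_rate_hz)) lfp_abort("sample_rate_hz must be positive", "lfpmon_validation_error")
  if (!is_count(samples_per_packet) || samples_per_packet < 1) {
    lfp_abort("samples_per_packet must be a positive integer", "lfpmon_validation_error")
  }
  if (!is_pos_num(scale_uv_per_bit)) lfp_abort("scale_uv_per_bit must be positive", "lfpmon_validation_error")
  if (!is_count(raw_offset_bits)) lfp_abort("raw_offset_bits must be a non-negative integer", "lfpmon_validation_error")
  if (!is_pos_num(nominal_frame_rate_hz)) lfp_abort("nominal_frame_rate_hz must be positive", "lfpmon_validation_error")
  animals <- lapply(animals, function(a) {
    if (inherits(a, "animal_channels")) a
    else animal_channels(a$animal_id, a$left_channel, a$right_channel)
  })
  ids <- vapply(animals, `[[`, character(1), "animal_id")
  if (anyDuplicated(ids)) {
    lfp_abort(sprintf("duplicate animal id(s): %s",
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")),
              "lfpmon_validation_error")
  }
  for (a in animals) {
    if (max(a$left_channel, a$right_channel) >= num_channels) {
      lfp_abort(sprintf("animal '%s' references channel >= num_channels (%d)",
                        a$animal_id, as.integer(num_channels)),
                "lfpmon_validation_error")
    }
  }
  structure(
    list(sample_rate_hz = as.double(sample_rate_hz),
         samples_per_packet = as.integer(samples_per_packet),
         num_channels = as.integer(num_channels),
         scale_uv_per_bit = as.double(scale_uv_per_bit),
         raw_offset_bits = as.integer(raw_offset_bits),
         nominal_frame_rate_hz = as.double(nominal_frame_rate_hz),
         layout = layout,
         ts_layout = ts_layout,
         animals = animals),
    class = "session_config"
  )
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf("<session_config> %g Hz, %d samples/packet, %d channels, %g uV/bit (offset %d)\n",
              x$sample_rate_hz, x$samples_per_packet, x$num_channels,
              x$scale_uv_per_bit, x$raw_offset_bits))
  for (a in x$animals) {
    cat(sprintf("  %s: L=ch%d R=ch%d\n", a$animal_id, a$left_channel, a$right_channel))
  }
  invisible(x)
}

config_fields_required <- c("num_channels")
config_fields_optional <- c("sample_rate_hz", "samples_per_packet", "scale_uv_per_bit",
                            "raw_offset_bits", "nominal_frame_rate_hz", "layout",
                            "ts_layout", "animals")

#' Parse a session config file
#'
#' The config is a JSON document with keys `num_channels` (required) and
#' optionally `sample_rate_hz`, `samples_per_packet`, `scale_uv_per_bit`,
#' `raw_offset_bits`, `nominal_frame_rate_hz`, `layout`, `ts_layout` and
#' `animals` (array of `{animal_id, left_channel, right_channel}`). Omitted
#' optional keys take the rig defaults.
#'
#' @param path Path to the JSON config file.
#' @return A [session_config()].
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) {
    lfp_abort(sprintf("config file not found: %s", path), "lfpmon_schema_error")
  }
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE),
    error = function(e) lfp_abort(sprintf("config is not valid JSON: %s", conditionMessage(e)),
                                  "lfpmon_schema_error")
  )
  if (!is.list(doc)) lfp_abort("config must be a JSON object", "lfpmon_schema_error")
  missing <- setdiff(config_fields_required, names(doc))
  if (length(missing)) {
    lfp_abort(sprintf("config missing required field(s): %s", paste(missing, collapse = ", ")),
              "lfpmon_schema_error")
  }
  unknown <- setdiff(names(doc), c(config_fields_required, config_fields_optional))
  if (length(unknown)) {
    lfp_abort(sprintf("config has unknown field(s): %s", paste(unknown, collapse = ", ")),
              "lfpmon_schema_error")
  }
  animals <- lapply(doc$animals, function(a) {
    need <- setdiff(c("animal_id", "left_channel", "right_channel"), names(a))
    if (length(need)) {
      lfp_abort(sprintf("animal entry missing field(s): %s", paste(need, collapse = ", ")),
                "lfpmon_schema_error")
    }
    animal_channels(a$animal_id, a$left_channel, a$right_channel)
  })
  args <- doc[setdiff(names(doc), "animals")]
  args$animals <- animals
  do.call(session_config, args)
}

#' Write a session config file
#'
#' Inverse of [parse_config()]; emits the JSON schema documented there.
#'
#' @param config A [session_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "session_config"))
  doc <- list(
    sample_rate_hz = config$sample_rate_hz,
    samples_per_packet = config$samples_per_packet,
    num_channels = config$num_channels,
    scale_uv_per_bit = config$scale_uv_per_bit,
    raw_offset_bits = config$raw_offset_bits,
    nominal_frame_rate_hz = config$nominal_frame_rate_hz,
    layout = config$layout,
    ts_layout = config$ts_layout,
    animals = lapply(config$animals, function(a) {
      list(animal_id = a$animal_id, left_channel = a$left_channel,
           right_channel = a$right_channel)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
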