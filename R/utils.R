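#' @keywords internal
"_PACKAGE"

# Condition helpers: every user-facing error carries a subclass so callers
# (and tests) can distinguish schema, format, validation and sync failures.
lfp_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "lfpmon_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

lfp_warn <- function(msg, class) {
  warning(structure(
    class = c(class, "lfpmon_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == trunc(x)
}

is_pos_num <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x > 0
}

# --- unsigned binary helpers ------------------------------------------------
# R has no native unsigned types; 16-bit values are mapped through the signed
# range on write and lifted back on read. 32-bit timestamps are carried as
# doubles (exact for anything below 2^53).

read_uint16 <- function(path) {
  n <- file.size(path)
  if (is.na(n)) lfp_abort(sprintf("file not found: %s", path), "lfpmon_format_error")
  if (n %% 2L != 0L) {
    lfp_abort(sprintf("file %s has odd byte length %d", path, n), "lfpmon_format_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "integer", n = n / 2, size = 2L, signed = FALSE, endian = "little")
  v
}

write_uint16 <- function(values, path) {
  if (any(values < 0 | values > 65535)) {
    lfp_abort("raw values outside the 16-bit unsigned range [0, 65535]", "lfpmon_range_error")
  }
  v <- as.integer(values)
  v[v >= 32768L] <- v[v >= 32768L] - 65536L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(v, con, size = 2L, endian = "little")
  invisible(path)
}

read_uint32 <- function(path) {
  n <- file.size(path)
  if (is.na(n)) lfp_abort(sprintf("file not found: %s", path), "lfpmon_format_error")
  if (n %% 4L != 0L) {
    lfp_abort(sprintf("file %s length %d is not a multiple of 4", path, n), "lfpmon_format_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "integer", n = n / 4, size = 4L, endian = "little")
  v <- as.double(v)
  v[v < 0] <- v[v < 0] + 2^32
  v
}

write_uint32 <- function(values, path) {
  if (any(values < 0 | values >= 2^32)) {
    lfp_abort("values outside the 32-bit unsigned range", "lfpmon_range_error")
  }
  v <- round(values)
  v[v >= 2^31] <- v[v >= 2^31] - 2^32
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(v), con, size = 4L, endian = "little")
  invisible(path)
}
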