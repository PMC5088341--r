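# Internal helpers: timestamp and boolean serialization conventions.
#
# Timestamps are ISO-8601 at minute resolution in a single study timezone
# (stored as UTC); booleans are serialized as "yes"/"no" to match
# questionnaire wording, parsed case-insensitively.

TIME_FMT <- "%Y-%m-%dT%H:%M"

format_instant <- function(x) {
  out <- format(x, format = TIME_FMT, tz = "UTC")
  out[is.na(x)] <- ""
  out
}

parse_instant <- function(x) {
  x <- trimws(as.character(x))
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  nonempty <- !is.na(x) & nzchar(x)
  parsed <- as.POSIXct(x[nonempty], format = TIME_FMT, tz = "UTC")
  # fall back to a space separator, still minute resolution
  retry <- is.na(parsed)
  if (any(retry)) {
    parsed[retry] <- as.POSIXct(x[nonempty][retry],
      format = "%Y-%m-%d %H:%M", tz = "UTC"
    )
  }
  out[nonempty] <- parsed
  attr(out, "failed") <- nonempty & is.na(out)
  out
}

# snap an instant to whole minutes so write -> read round-trips exactly
floor_minute <- function(x) {
  as.POSIXct(floor(as.numeric(x) / 60) * 60, origin = "1970-01-01", tz = "UTC")
}

format_yesno <- function(x) ifelse(x, "yes", "no")

parse_yesno <- function(x) {
  lowered <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[lowered %in% c("yes", "true", "1")] <- TRUE
  out[lowered %in% c("no", "false", "0")] <- FALSE
  out
}

validation_abort <- function(msg, ...) {
  abort(msg, class = "emalapse_validation_error", ...)
}

io_abort <- function(msg, ...) {
  abort(msg, class = "emalapse_io_error", ...)
}

# error message pinpointing file / line / column for malformed delimited input
field_abort <- function(file, line, column, detail) {
  validation_abort(sprintf(
    "Invalid value in '%s', line %d, column '%s': %s",
    file, line, column, detail
  ))
}
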