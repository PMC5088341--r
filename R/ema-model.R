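#' EMA cohorts: domain types, validation and delimited-text I/O
#'
#' An `ema_cohort` bundles a participant roster with the momentary
#' assessments (EMAs) completed by those participants. Each EMA carries four
#' 5-point ordinal items (urge to smoke, stress, cessation motivation,
#' cigarette availability; 1 = strongly disagree / "not at all",
#' 5 = strongly agree / "easily available"), two binary items (interacting
#' with someone smoking, alcohol within the last hour), a momentary smoking
#' report, a prompt type and a minute-resolution timestamp. The roster carries
#' each participant's treatment arm, quit time, first-lapse time (if any) and
#' a reporting-consistency flag; participants flagged inconsistent are
#' excluded from every analysis set.
#'
#' @param participants Tibble with columns `participant_id`, `arm`
#'   (`"UC"` or `"CM"`), `quit_time`, `first_lapse_time` (`NA` for
#'   abstainers), `consistent_reporting`.
#' @param records Tibble with columns `participant_id`, `timestamp`,
#'   `prompt_type` (one of `daily_diary`, `random`, `urge_selfinit`,
#'   `lapse_selfinit`), `urge`, `stress`, `motivation`, `availability`
#'   (integers 1-5), `interacting_smoker`, `alcohol_past_hour`,
#'   `smoked_since_last` (logical).
#'
#' @return An object of class `ema_cohort`: a list with elements
#'   `participants` and `records`, both tibbles, plus a derived logical
#'   `lapsed` column on the roster.
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(n_lapsers = 2, n_abstainers = 2))
#' cohort
ema_cohort <- function(participants, records) {
  participants <- tibble::as_tibble(participants)
  records <- tibble::as_tibble(records)
  # normalize the tzone attribute so round-trips compare field-for-field
  as_utc <- function(x) {
    attr(x, "tzone") <- "UTC"
    x
  }
  participants$quit_time <- as_utc(participants$quit_time)
  participants$first_lapse_time <- as_utc(participants$first_lapse_time)
  records$timestamp <- as_utc(records$timestamp)
  participants$lapsed <- !is.na(participants$first_lapse_time)
  out <- structure(
    list(participants = participants, records = records),
    class = "ema_cohort"
  )
  validate_cohort(out)
  out
}

#' @export
print.ema_cohort <- function(x, ...) {
  n_lap <- sum(x$participants$lapsed)
  cat(sprintf(
    "<ema_cohort> %d participants (%d lapsers, %d abstainers), %d EMA records\n",
    nrow(x$participants), n_lap, nrow(x$participants) - n_lap, nrow(x$records)
  ))
  invisible(x)
}

validate_cohort <- function(cohort) {
  p <- cohort$participants
  r <- cohort$records
  if (anyDuplicated(p$participant_id)) {
    validation_abort("duplicated participant_id in roster")
  }
  bad_arm <- !p$arm %in% c("UC", "CM")
  if (any(bad_arm)) {
    validation_abort(sprintf(
      "unknown arm '%s' for participant '%s'",
      p$arm[bad_arm][1], p$participant_id[bad_arm][1]
    ))
  }
  if (any(is.na(p$quit_time))) {
    validation_abort("missing quit_time in roster")
  }
  early <- !is.na(p$first_lapse_time) & p$first_lapse_time < p$quit_time
  if (any(early)) {
    validation_abort(sprintf(
      "first_lapse_time precedes quit_time for participant '%s'",
      p$participant_id[early][1]
    ))
  }
  orphan <- !r$participant_id %in% p$participant_id
  if (any(orphan)) {
    validation_abort(sprintf(
      "EMA record references unknown participant_id '%s'",
      r$participant_id[orphan][1]
    ))
  }
  if (any(is.na(r$timestamp))) {
    validation_abort("missing or unparseable EMA timestamp")
  }
  bad_prompt <- !r$prompt_type %in% PROMPT_TYPES
  if (any(bad_prompt)) {
    validation_abort(sprintf("unknown prompt_type '%s'", r$prompt_type[bad_prompt][1]))
  }
  for (col in c("urge", "stress", "motivation", "availability")) {
    v <- r[[col]]
    bad <- is.na(v) | v < 1L | v > 5L | v != as.integer(v)
    if (any(bad)) {
      validation_abort(sprintf(
        "ordinal item '%s' outside 1-5 (value %s)", col, as.character(v[bad][1])
      ))
    }
  }
  for (col in c("interacting_smoker", "alcohol_past_hour", "smoked_since_last")) {
    if (any(is.na(r[[col]]))) {
      validation_abort(sprintf("missing boolean item '%s'", col))
    }
  }
  invisible(cohort)
}

EMA_COLUMNS <- c(
  "participant_id", "timestamp", "prompt_type", "urge", "stress",
  "motivation", "availability", "interacting_smoker", "alcohol_past_hour",
  "smoked_since_last"
)

ROSTER_COLUMNS <- c(
  "participant_id", "arm", "quit_time", "first_lapse_time",
  "consistent_reporting"
)

#' Read an EMA cohort from a pair of CSV files
#'
#' Reads the EMA table and participant roster written by [write_cohort()]
#' (or produced externally to the same schema), validating every field.
#' Malformed values raise an error naming the file, line and column; an EMA
#' row whose `participant_id` is absent from the roster is an error. Row
#' order is preserved and timestamps are normalized to a single timezone.
#'
#' @param ema_path Path to the EMA CSV (columns, in order: `participant_id`,
#'   `timestamp`, `prompt_type`, `urge`, `stress`, `motivation`,
#'   `availability`, `interacting_smoker`, `alcohol_past_hour`,
#'   `smoked_since_last`).
#' @param roster_path Path to the roster CSV (columns: `participant_id`,
#'   `arm`, `quit_time`, `first_lapse_time` — empty for abstainers —
#'   `consistent_reporting`).
#' @return An [ema_cohort()].
#' @export
read_cohort <- function(ema_path, roster_path) {
  for (path in c(ema_path, roster_path)) {
    if (!file.exists(path)) io_abort(sprintf("file not found: '%s'", path))
  }
  raw_r <- readr::read_csv(roster_path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  raw_e <- readr::read_csv(ema_path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  check_columns <- function(raw, expected, path) {
    missing <- setdiff(expected, names(raw))
    if (length(missing)) {
      io_abort(sprintf(
        "'%s' is missing required column(s): %s",
        path, paste(missing, collapse = ", ")
      ))
    }
  }
  check_columns(raw_r, ROSTER_COLUMNS, roster_path)
  check_columns(raw_e, EMA_COLUMNS, ema_path)

  participants <- parse_roster(raw_r, roster_path)
  records <- parse_ema(raw_e, ema_path)
  ema_cohort(participants, records)
}

parse_roster <- function(raw, path) {
  n <- nrow(raw)
  line <- seq_len(n) + 1L # header is line 1
  parse_time_col <- function(col, required) {
    parsed <- parse_instant(raw[[col]])
    failed <- attr(parsed, "failed")
    if (required) failed <- failed | is.na(raw[[col]]) | !nzchar(trimws(raw[[col]]))
    if (any(failed)) {
      field_abort(path, line[failed][1], col, sprintf(
        "expected ISO-8601 timestamp (YYYY-MM-DDTHH:MM), got '%s'",
        as.character(raw[[col]][failed][1])
      ))
    }
    attr(parsed, "failed") <- NULL
    parsed
  }
  quit_time <- parse_time_col("quit_time", required = TRUE)
  first_lapse_time <- parse_time_col("first_lapse_time", required = FALSE)
  consistent <- parse_yesno(raw$consistent_reporting)
  if (any(is.na(consistent))) {
    i <- which(is.na(consistent))[1]
    field_abort(path, line[i], "consistent_reporting", sprintf(
      "expected yes/no, got '%s'", as.character(raw$consistent_reporting[i])
    ))
  }
  bad_arm <- !raw$arm %in% c("UC", "CM")
  if (any(bad_arm)) {
    field_abort(path, line[bad_arm][1], "arm", sprintf(
      "expected UC or CM, got '%s'", as.character(raw$arm[bad_arm][1])
    ))
  }
  tibble::tibble(
    participant_id = raw$participant_id,
    arm = raw$arm,
    quit_time = quit_time,
    first_lapse_time = first_lapse_time,
    consistent_reporting = consistent
  )
}

parse_ema <- function(raw, path) {
  n <- nrow(raw)
  line <- seq_len(n) + 1L
  timestamp <- parse_instant(raw$timestamp)
  failed <- attr(timestamp, "failed") | is.na(timestamp)
  if (any(failed)) {
    field_abort(path, line[failed][1], "timestamp", sprintf(
      "expected ISO-8601 timestamp, got '%s'", as.character(raw$timestamp[failed][1])
    ))
  }
  attr(timestamp, "failed") <- NULL
  bad_prompt <- !raw$prompt_type %in% PROMPT_TYPES
  if (any(bad_prompt)) {
    field_abort(path, line[bad_prompt][1], "prompt_type", sprintf(
      "expected one of %s, got '%s'",
      paste(PROMPT_TYPES, collapse = "/"), as.character(raw$prompt_type[bad_prompt][1])
    ))
  }
  ordinals <- lapply(c("urge", "stress", "motivation", "availability"), function(col) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    bad <- is.na(v) | v < 1L | v > 5L | as.character(v) != trimws(raw[[col]])
    if (any(bad)) {
      field_abort(path, line[bad][1], col, sprintf(
        "expected an integer in 1-5, got '%s'", as.character(raw[[col]][bad][1])
      ))
    }
    v
  })
  names(ordinals) <- c("urge", "stress", "motivation", "availability")
  bools <- lapply(
    c("interacting_smoker", "alcohol_past_hour", "smoked_since_last"),
    function(col) {
      v <- parse_yesno(raw[[col]])
      if (any(is.na(v))) {
        i <- which(is.na(v))[1]
        field_abort(path, line[i], col, sprintf(
          "expected yes/no, got '%s'", as.character(raw[[col]][i])
        ))
      }
      v
    }
  )
  names(bools) <- c("interacting_smoker", "alcohol_past_hour", "smoked_since_last")
  tibble::tibble(
    participant_id = raw$participant_id,
    timestamp = timestamp,
    prompt_type = raw$prompt_type,
    urge = ordinals$urge,
    stress = ordinals$stress,
    motivation = ordinals$motivation,
    availability = ordinals$availability,
    interacting_smoker = bools$interacting_smoker,
    alcohol_past_hour = bools$alcohol_past_hour,
    smoked_since_last = bools$smoked_since_last
  )
}

#' Write an EMA cohort to a pair of CSV files
#'
#' Inverse of [read_cohort()]: `read_cohort()` applied to the written files
#' reproduces the cohort field-for-field. Timestamps are serialized as
#' ISO-8601 at minute resolution; booleans as `yes`/`no`.
#'
#' @param cohort An [ema_cohort()].
#' @inheritParams read_cohort
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, ema_path, roster_path) {
  validate_cohort(cohort)
  p <- cohort$participants
  roster_out <- data.frame(
    participant_id = p$participant_id,
    arm = p$arm,
    quit_time = format_instant(p$quit_time),
    first_lapse_time = format_instant(p$first_lapse_time),
    consistent_reporting = format_yesno(p$consistent_reporting),
    stringsAsFactors = FALSE
  )
  r <- cohort$records
  ema_out <- data.frame(
    participant_id = r$participant_id,
    timestamp = format_instant(r$timestamp),
    prompt_type = r$prompt_type,
    urge = r$urge,
    stress = r$stress,
    motivation = r$motivation,
    availability = r$availability,
    interacting_smoker = format_yesno(r$interacting_smoker),
    alcohol_past_hour = format_yesno(r$alcohol_past_hour),
    smoked_since_last = format_yesno(r$smoked_since_last),
    stringsAsFactors = FALSE
  )
  tryCatch(
    {
      readr::write_csv(roster_out, roster_path, progress = FALSE)
      readr::write_csv(ema_out, ema_path, progress = FALSE)
    },
    error = function(e) io_abort(conditionMessage(e))
  )
  invisible(c(ema = ema_path, roster = roster_path))
}
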