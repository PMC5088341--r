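#' Proximity-window configuration
#'
#' Houses the look-ahead window defining "imminent" lapse: an EMA is
#' imminent-lapse if it falls within `window_hours` before the first lapse.
#' The study value is 4 hours.
#'
#' @param window_hours Positive window length in hours (default 4).
#' @return A list of class `window_config`.
#' @export
window_config <- function(window_hours = 4) {
  if (!is.numeric(window_hours) || length(window_hours) != 1L ||
    is.na(window_hours) || window_hours <= 0) {
    validation_abort("window_hours must be a single positive number")
  }
  structure(list(window_hours = window_hours), class = "window_config")
}

#' Label EMA records by proximity to the first lapse
#'
#' Assigns each record exactly one of five labels: `WITHIN_4H` (lapser,
#' within the window before the first lapse, boundary inclusive),
#' `PRE_LAPSE_OVER_4H` (lapser, earlier than the window), `ABSTAINER`
#' (participant never lapsed), `EXCLUDED_POST_LAPSE` (at or after the first
#' lapse — the lapse-moment EMA itself is not a predictor observation), or
#' `EXCLUDED_INCONSISTENT` (participant flagged as an inconsistent
#' reporter, which overrides everything else). Only the first three labels
#' enter analyses.
#'
#' @param timestamp POSIXct vector of EMA times.
#' @param first_lapse_time POSIXct vector (NA for abstainers), recycled or
#'   matched to `timestamp`.
#' @param consistent_reporting Logical vector, recycled likewise.
#' @param config A [window_config()].
#' @return A factor with levels `WITHIN_4H`, `PRE_LAPSE_OVER_4H`,
#'   `ABSTAINER`, `EXCLUDED_POST_LAPSE`, `EXCLUDED_INCONSISTENT`.
#' @export
#' @examples
#' lapse <- as.POSIXct("2011-08-03 18:00", tz = "UTC")
#' ema <- as.POSIXct(c("2011-08-03 15:00", "2011-08-03 13:00", "2011-08-03 19:00"), tz = "UTC")
#' label_proximity(ema, rep(lapse, 3), rep(TRUE, 3))
label_proximity <- function(timestamp, first_lapse_time, consistent_reporting,
                            config = window_config()) {
  if (any(is.na(timestamp))) {
    validation_abort("missing EMA timestamp")
  }
  n <- length(timestamp)
  first_lapse_time <- rep_len(first_lapse_time, n)
  consistent_reporting <- rep_len(consistent_reporting, n)
  window_sec <- config$window_hours * 3600

  gap <- as.numeric(first_lapse_time) - as.numeric(timestamp) # > 0 if pre-lapse
  label <- ifelse(
    is.na(first_lapse_time), "ABSTAINER",
    ifelse(
      gap <= 0, "EXCLUDED_POST_LAPSE",
      ifelse(gap <= window_sec, "WITHIN_4H", "PRE_LAPSE_OVER_4H")
    )
  )
  label[!consistent_reporting] <- "EXCLUDED_INCONSISTENT"
  factor(label, levels = PROXIMITY_LEVELS)
}

#' Build the analysis set of pre-lapse and abstainer EMAs
#'
#' Selects, from a cohort, the records that enter every downstream
#' analysis: all pre-lapse EMAs of lapsers (labelled `WITHIN_4H` or
#' `PRE_LAPSE_OVER_4H`) and all EMAs of abstainers (`ABSTAINER`).
#' Records at or after the first lapse and records of inconsistent
#' reporters are excluded; records stamped before the participant's quit
#' time are dropped with a warning (the pre-quit week is out of scope).
#' Per-label counts are attached as attribute `"label_counts"` and
#' reported via a message.
#'
#' @param cohort An [ema_cohort()].
#' @param config A [window_config()].
#' @param quiet Suppress the count message.
#' @return A tibble: all EMA columns, the participant's `arm`, `quit_time`,
#'   `first_lapse_time` and `lapsed`, plus `proximity_label` (retained
#'   labels only).
#' @export
build_analysis_set <- function(cohort, config = window_config(), quiet = FALSE) {
  validate_cohort(cohort)
  joined <- dplyr::left_join(
    cohort$records,
    cohort$participants[, c(
      "participant_id", "arm", "quit_time", "first_lapse_time",
      "consistent_reporting", "lapsed"
    )],
    by = "participant_id"
  )

  prequit <- joined$timestamp < joined$quit_time
  if (any(prequit)) {
    warn(sprintf(
      "dropping %d EMA record(s) stamped before quit_time (pre-quit period is out of scope)",
      sum(prequit)
    ))
    joined <- joined[!prequit, ]
  }

  joined$proximity_label <- label_proximity(
    joined$timestamp, joined$first_lapse_time, joined$consistent_reporting,
    config
  )
  counts <- table(joined$proximity_label)
  if (!quiet) {
    inform(sprintf(
      "analysis set: %d within-window, %d pre-lapse beyond window, %d abstainer; excluded %d post-lapse, %d inconsistent",
      counts[["WITHIN_4H"]], counts[["PRE_LAPSE_OVER_4H"]], counts[["ABSTAINER"]],
      counts[["EXCLUDED_POST_LAPSE"]], counts[["EXCLUDED_INCONSISTENT"]]
    ))
  }

  retained <- joined[joined$proximity_label %in% ANALYSIS_LEVELS, ]
  retained$proximity_label <- factor(
    as.character(retained$proximity_label),
    levels = ANALYSIS_LEVELS
  )
  retained$consistent_reporting <- NULL
  attr(retained, "label_counts") <- counts
  retained
}
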