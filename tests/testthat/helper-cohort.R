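# fixtures are built in code: tiny hand-assembled cohorts and
# synthetic record tables used across the suite

utc <- function(x) as.POSIXct(x, tz = "UTC")

make_roster <- function(ids, lapse_times = NULL, arm = "UC",
                        quit = "2011-08-01 00:00", consistent = TRUE) {
  n <- length(ids)
  lt <- if (is.null(lapse_times)) rep(NA_character_, n) else lapse_times
  tibble::tibble(
    participant_id = ids,
    arm = rep_len(arm, n),
    quit_time = utc(rep_len(quit, n)),
    first_lapse_time = utc(lt),
    consistent_reporting = rep_len(consistent, n)
  )
}

make_records <- function(ids, times, urge = 3L, stress = 3L, motivation = 3L,
                         availability = 3L, smoker = FALSE, alcohol = FALSE,
                         smoked = FALSE, prompt = "random") {
  n <- length(times)
  tibble::tibble(
    participant_id = rep_len(ids, n),
    timestamp = utc(times),
    prompt_type = rep_len(prompt, n),
    urge = as.integer(rep_len(urge, n)),
    stress = as.integer(rep_len(stress, n)),
    motivation = as.integer(rep_len(motivation, n)),
    availability = as.integer(rep_len(availability, n)),
    interacting_smoker = rep_len(smoker, n),
    alcohol_past_hour = rep_len(alcohol, n),
    smoked_since_last = rep_len(smoked, n)
  )
}

# all 5^4 x 2^2 = 2,500 response profiles
all_profiles <- function() {
  expand.grid(
    urge = 1:5, stress = 1:5, motivation = 1:5, availability = 1:5,
    interacting_smoker = c(FALSE, TRUE), alcohol_past_hour = c(FALSE, TRUE),
    KEEP.OUT.ATTRS = FALSE
  )
}

# random labeled item tables (not tied to any sampling design)
random_labeled_records <- function(n, seed, p_within = 0.3) {
  set.seed(seed)
  d <- tibble::tibble(
    participant_id = sprintf("P%02d", sample.int(20, n, replace = TRUE)),
    arm = "UC",
    urge = sample(1:5, n, TRUE),
    stress = sample(1:5, n, TRUE),
    motivation = sample(1:5, n, TRUE),
    availability = sample(1:5, n, TRUE),
    interacting_smoker = runif(n) < 0.3,
    alcohol_past_hour = runif(n) < 0.2,
    proximity_label = factor(
      ifelse(runif(n) < p_within, "WITHIN_4H", "ABSTAINER"),
      levels = c("WITHIN_4H", "PRE_LAPSE_OVER_4H", "ABSTAINER")
    )
  )
  d
}

# records in which the only real signal is the centered availability item;
# used for planted-weight recovery and its label-permuted null
planted_signal_records <- function(n, seed, permute_labels = FALSE) {
  set.seed(seed)
  d <- tibble::tibble(
    participant_id = sprintf("P%03d", sample.int(50, n, replace = TRUE)),
    urge = sample(1:5, n, TRUE),
    stress = sample(1:5, n, TRUE),
    motivation = sample(1:5, n, TRUE),
    availability = sample(1:5, n, TRUE),
    interacting_smoker = runif(n) < 0.3,
    alcohol_past_hour = runif(n) < 0.3
  )
  positive <- runif(n) < stats::plogis(2.5 * (d$availability - 3))
  if (permute_labels) positive <- sample(positive)
  d$proximity_label <- factor(
    ifelse(positive, "WITHIN_4H", "ABSTAINER"),
    levels = c("WITHIN_4H", "PRE_LAPSE_OVER_4H", "ABSTAINER")
  )
  d
}

# success predicate for planted-weight recovery: the Youden objective is
# invariant to rescaling all weights and the cut-off together, so coefficients
# are identified only up to a common positive factor; a noise binary sitting
# exactly at a flagging boundary can tie the leading coefficient. Recovery
# therefore means: availability strictly dominates the other ordinal items
# and no coefficient exceeds it.
recovered_availability <- function(w) {
  ordinals <- c(w$w_urge, w$w_stress, w$w_motivation)
  binaries <- c(w$w_smoker_present, w$w_alcohol)
  w$w_availability > max(ordinals) && w$w_availability >= max(binaries)
}

dichotomize_items <- function(items) {
  dichotomize(
    items$urge, items$stress, items$motivation, items$availability,
    items$interacting_smoker, items$alcohol_past_hour
  )
}

# O(n^2) pairwise AUC oracle, independent of the rank implementation
auc_pairwise_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

trapezoid_area <- function(curve) {
  sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
}
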