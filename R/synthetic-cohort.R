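#' Simulation configuration for a synthetic EMA cohort
#'
#' Defines the sampling design and the group-conditional risk-factor
#' structure used by [generate_cohort()]. Defaults emulate the motivating
#' study: 52 lapsers and 40 abstainers followed for 7 post-quit days with
#' five prompted EMAs per day (one wake-anchored daily diary 30 minutes
#' after waking plus four random prompts over a 16-hour waking window),
#' participant-initiated EMAs, and per-factor prevalences conditional on
#' lapse proximity (within 4 hours of the first lapse, more than 4 hours
#' before it, or abstainer).
#'
#' The three prevalence vectors are ordered
#' (urge, stress, low motivation, cigarette availability,
#' interacting with a smoker, recent alcohol), each entry the probability
#' that the dichotomized indicator is positive for an EMA of that proximity
#' class.
#'
#' @param n_lapsers,n_abstainers Participant counts (defaults 52 and 40).
#' @param days_postquit Length of the observed post-quit period in days.
#' @param prompts_per_day Prompted EMAs per day (1 diary + the rest random).
#' @param waking_window_hours Waking-window length in hours.
#' @param selfinit_rate_per_day Poisson rate of urge-triggered self-initiated
#'   EMAs per participant-day.
#' @param compliance_prob Probability a prompted EMA is completed.
#' @param prevalence_within4h,prevalence_over4h,prevalence_abstainer
#'   Length-6 indicator prevalence vectors by proximity class.
#' @param latent_correlation Correlation in `[0, 1)` induced among the six
#'   indicators by one shared Gaussian copula factor; 0 means independent.
#' @param inconsistent_fraction Fraction of participants flagged as
#'   inconsistent reporters (excluded from analyses).
#' @param lapse_report_prob Probability a lapser files a `lapse_selfinit`
#'   EMA shortly before the lapse.
#' @param lapse_report_window_minutes The lapse-report EMA is placed
#'   uniformly within this many minutes before the lapse.
#' @param master_seed Integer seed; all randomness flows from it through
#'   per-participant substreams.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_lapsers = 52L,
                       n_abstainers = 40L,
                       days_postquit = 7L,
                       prompts_per_day = 5L,
                       waking_window_hours = 16,
                       selfinit_rate_per_day = 1.6,
                       compliance_prob = 0.9,
                       prevalence_within4h = c(0.593, 0.411, 0.173, 0.748, 0.336, 0.191),
                       prevalence_over4h = c(0.491, 0.188, 0.151, 0.704, 0.129, 0.189),
                       prevalence_abstainer = c(0.328, 0.259, 0.010, 0.526, 0.121, 0.034),
                       latent_correlation = 0,
                       inconsistent_fraction = 0,
                       lapse_report_prob = 0.9,
                       lapse_report_window_minutes = 30,
                       master_seed = 1L) {
  cfg <- list(
    n_lapsers = as.integer(n_lapsers),
    n_abstainers = as.integer(n_abstainers),
    days_postquit = as.integer(days_postquit),
    prompts_per_day = as.integer(prompts_per_day),
    waking_window_hours = waking_window_hours,
    selfinit_rate_per_day = selfinit_rate_per_day,
    compliance_prob = compliance_prob,
    prevalence_within4h = prevalence_within4h,
    prevalence_over4h = prevalence_over4h,
    prevalence_abstainer = prevalence_abstainer,
    latent_correlation = latent_correlation,
    inconsistent_fraction = inconsistent_fraction,
    lapse_report_prob = lapse_report_prob,
    lapse_report_window_minutes = lapse_report_window_minutes,
    master_seed = as.integer(master_seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_lapsers < 0L || cfg$n_abstainers < 0L ||
    cfg$n_lapsers + cfg$n_abstainers < 1L) {
    validation_abort("participant counts must be non-negative and sum to >= 1")
  }
  if (cfg$days_postquit < 1L || cfg$prompts_per_day < 1L) {
    validation_abort("days_postquit and prompts_per_day must be positive")
  }
  if (cfg$waking_window_hours <= 0) {
    validation_abort("waking_window_hours must be positive")
  }
  for (nm in c(
    "compliance_prob", "inconsistent_fraction", "lapse_report_prob"
  )) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      validation_abort(sprintf("%s must lie in [0, 1]", nm))
    }
  }
  if (cfg$latent_correlation < 0 || cfg$latent_correlation >= 1) {
    validation_abort("latent_correlation must lie in [0, 1)")
  }
  for (nm in c(
    "prevalence_within4h", "prevalence_over4h", "prevalence_abstainer"
  )) {
    p <- cfg[[nm]]
    if (length(p) != 6L) {
      validation_abort(sprintf("%s must have exactly 6 entries", nm))
    }
    if (any(p < 0 | p > 1)) {
      validation_abort(sprintf("%s entries must lie in [0, 1]", nm))
    }
  }
  invisible(cfg)
}

#' Map a target indicator prevalence onto a 5-category ordinal distribution
#'
#' The study reports risk factors only after dichotomization; to generate
#' full 1-5 ordinal responses whose dichotomized indicator has a specified
#' prevalence, the indicator-positive mass `p` is placed on the positive
#' categories with a fixed split, and the remaining mass on the others:
#' for agree-keyed items (`urge`, `stress`, `availability`) positive mass
#' splits 60/40 over categories 4/5 and negative mass 20/40/40 over 1/2/3;
#' for `motivation` (indicator positive when the response is 1 or 2) the
#' split is mirrored. Only the dichotomized mass matters downstream.
#'
#' @param p Target prevalence of the positive indicator, in `[0, 1]`.
#' @param item One of `"urge"`, `"stress"`, `"motivation"`, `"availability"`.
#' @return A list of class `ordinal_map` with `probs` (named category
#'   masses, summing to 1), `positive_categories` and `risk_order` (the
#'   categories ordered least- to most-risky, used so a shared copula
#'   factor pushes every item toward risk jointly).
#' @export
#' @examples
#' map_prevalence_to_ordinal(0.593, "urge")$probs
map_prevalence_to_ordinal <- function(p, item = c(
                                        "urge", "stress", "motivation",
                                        "availability"
                                      )) {
  item <- match.arg(item)
  if (is.na(p) || p < 0 || p > 1) validation_abort("prevalence must lie in [0, 1]")
  q <- 1 - p
  if (item == "motivation") {
    probs <- c(`1` = 0.4 * p, `2` = 0.6 * p, `3` = 0.4 * q, `4` = 0.4 * q, `5` = 0.2 * q)
    positive <- c(1L, 2L)
    risk_order <- c(5L, 4L, 3L, 2L, 1L)
  } else {
    probs <- c(`1` = 0.2 * q, `2` = 0.4 * q, `3` = 0.4 * q, `4` = 0.6 * p, `5` = 0.4 * p)
    positive <- c(4L, 5L)
    risk_order <- 1:5
  }
  structure(
    list(
      item = item, prevalence = p, probs = probs,
      positive_categories = positive, risk_order = risk_order
    ),
    class = "ordinal_map"
  )
}

# Draw ordinal categories from an ordinal_map given uniforms; u near 1 always
# lands in the riskiest categories, so shared-factor uniforms induce positive
# correlation between the dichotomized indicators.
draw_ordinal <- function(map, u) {
  cum <- cumsum(map$probs[as.character(map$risk_order)])
  idx <- findInterval(u, cum, left.open = TRUE) + 1L
  idx[idx > 5L] <- 5L
  map$risk_order[idx]
}

# uniforms for one record's six items under a shared Gaussian factor
copula_uniforms <- function(n_records, rho) {
  if (rho == 0) {
    matrix(runif(n_records * 6L), nrow = n_records, ncol = 6L)
  } else {
    z <- rnorm(n_records)
    e <- matrix(rnorm(n_records * 6L), nrow = n_records)
    pnorm(sqrt(rho) * z + sqrt(1 - rho) * e)
  }
}

# draw the six items for n records of one proximity class
draw_items <- function(n, prev, rho) {
  u <- copula_uniforms(n, rho)
  maps <- list(
    urge = map_prevalence_to_ordinal(prev[1], "urge"),
    stress = map_prevalence_to_ordinal(prev[2], "stress"),
    motivation = map_prevalence_to_ordinal(prev[3], "motivation"),
    availability = map_prevalence_to_ordinal(prev[4], "availability")
  )
  tibble::tibble(
    urge = draw_ordinal(maps$urge, u[, 1]),
    stress = draw_ordinal(maps$stress, u[, 2]),
    motivation = draw_ordinal(maps$motivation, u[, 3]),
    availability = draw_ordinal(maps$availability, u[, 4]),
    interacting_smoker = u[, 5] > 1 - prev[5],
    alcohol_past_hour = u[, 6] > 1 - prev[6]
  )
}

# 4 random prompt times (minutes into the waking window) with >= 90 min
# spacing, emulating signal-contingent prompts "roughly every 4 hours"
random_prompt_minutes <- function(n_random, window_min, spacing = 90) {
  if (n_random == 0L) {
    return(numeric(0))
  }
  for (i in 1:1000) {
    t <- sort(runif(n_random, 0, window_min))
    if (n_random == 1L || min(diff(t)) >= spacing) {
      return(t)
    }
  }
  # spacing infeasible for this window; fall back to evenly spread jitter
  seq(0, window_min, length.out = n_random + 2L)[2:(n_random + 1L)]
}

#' Generate a seeded synthetic EMA cohort
#'
#' Simulates a cohort with the study's sampling design. Each lapser receives
#' a first-lapse time uniform over the waking portions of the post-quit
#' week, excluding the first 4 waking hours so that a pre-lapse window
#' exists. Each EMA's six items are drawn from the prevalence vector
#' matching the proximity class the EMA will eventually fall into (within
#' 4 h of the lapse, more than 4 h before it, or abstainer), through
#' [map_prevalence_to_ordinal()] so the downstream dichotomization rule
#' recovers the configured prevalences; post-lapse EMAs (excluded from all
#' analyses) reuse the over-4-hour vector. An optional shared Gaussian
#' copula factor induces positive inter-item correlation. A
#' `lapse_selfinit` EMA is placed shortly before each lapse with
#' configurable probability, and `smoked_since_last` turns true at and
#' after the lapse. Fully deterministic given `master_seed`, using
#' per-participant substreams.
#'
#' @param config A [sim_config()].
#' @return An [ema_cohort()]; attribute `"class_counts"` tallies generated
#'   records by intended proximity class (generator bookkeeping used by
#'   conservation checks).
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(n_lapsers = 3, n_abstainers = 2, master_seed = 7))
#' attr(cohort, "class_counts")
generate_cohort <- function(config) {
  validate_sim_config(config)
  cfg <- config
  n_total <- cfg$n_lapsers + cfg$n_abstainers
  ids <- c(
    sprintf("L%03d", seq_len(cfg$n_lapsers)),
    sprintf("A%03d", seq_len(cfg$n_abstainers))
  )
  is_lapser <- c(rep(TRUE, cfg$n_lapsers), rep(FALSE, cfg$n_abstainers))

  # per-participant substreams derived once from the master seed
  set.seed(cfg$master_seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_total + 1L)
  arm <- sample(c("UC", "CM"), n_total, replace = TRUE)
  inconsistent <- runif(n_total) < cfg$inconsistent_fraction

  origin <- as.POSIXct("2011-08-01 00:00", tz = "UTC")
  wake_min <- 8 * 60 # waking window starts 08:00
  window_min <- cfg$waking_window_hours * 60
  day_min <- 24 * 60
  quit_time <- origin # quit takes effect at the start of day 1

  window_h <- 4 # proximity window used to pick the generating prevalence

  participants <- vector("list", n_total)
  records <- vector("list", n_total)
  class_counts <- c(
    WITHIN_4H = 0L, PRE_LAPSE_OVER_4H = 0L, ABSTAINER = 0L,
    EXCLUDED_POST_LAPSE = 0L, EXCLUDED_INCONSISTENT = 0L
  )

  for (i in seq_len(n_total)) {
    set.seed(sub_seeds[i])
    # first-lapse time: uniform over waking minutes of days 1..days_postquit,
    # excluding the first `window_h` waking hours of day 1
    lapse_min <- NA_real_
    if (is_lapser[i]) {
      total_waking <- cfg$days_postquit * window_min - window_h * 60
      u <- runif(1, 0, total_waking) + window_h * 60
      day <- floor(u / window_min)
      # floored to the minute so roster and record times share one resolution
      lapse_min <- floor(day * day_min + wake_min + (u - day * window_min))
    }

    # prompted EMAs: diary at wake + 30 min, the rest random with spacing
    n_random <- cfg$prompts_per_day - 1L
    times <- unlist(lapply(seq_len(cfg$days_postquit) - 1L, function(day) {
      prompt <- c(30, random_prompt_minutes(n_random, window_min))
      completed <- runif(length(prompt)) < cfg$compliance_prob
      day * day_min + wake_min + prompt[completed]
    }))
    types <- rep("random", length(times))
    types[(times %% day_min) == wake_min + 30] <- "daily_diary"

    # urge-triggered self-initiated EMAs
    n_self <- rpois(1, cfg$selfinit_rate_per_day * cfg$days_postquit)
    if (n_self > 0) {
      day <- sample.int(cfg$days_postquit, n_self, replace = TRUE) - 1L
      t_self <- day * day_min + wake_min + runif(n_self, 0, window_min)
      times <- c(times, t_self)
      types <- c(types, rep("urge_selfinit", n_self))
    }

    # lapse-report EMA shortly before the lapse
    if (is_lapser[i] && runif(1) < cfg$lapse_report_prob) {
      t_rep <- lapse_min - runif(1, 0, cfg$lapse_report_window_minutes)
      if (t_rep > 0) {
        times <- c(times, t_rep)
        types <- c(types, "lapse_selfinit")
      }
    }

    participants[[i]] <- tibble::tibble(
      participant_id = ids[i],
      arm = arm[i],
      quit_time = quit_time,
      first_lapse_time = if (is_lapser[i]) {
        origin + lapse_min * 60
      } else {
        as.POSIXct(NA, origin = "1970-01-01", tz = "UTC")
      },
      consistent_reporting = !inconsistent[i]
    )

    ord <- order(times)
    times <- floor(times[ord]) # minute resolution
    types <- types[ord]
    n_rec <- length(times)
    if (n_rec == 0L) next

    # intended proximity class of each record drives its item distribution
    if (is_lapser[i]) {
      cls <- ifelse(
        times >= lapse_min, "EXCLUDED_POST_LAPSE",
        ifelse(lapse_min - times <= window_h * 60, "WITHIN_4H", "PRE_LAPSE_OVER_4H")
      )
    } else {
      cls <- rep("ABSTAINER", n_rec)
    }
    prev_of <- list(
      WITHIN_4H = cfg$prevalence_within4h,
      PRE_LAPSE_OVER_4H = cfg$prevalence_over4h,
      ABSTAINER = cfg$prevalence_abstainer,
      EXCLUDED_POST_LAPSE = cfg$prevalence_over4h
    )
    items <- tibble::tibble(
      urge = integer(n_rec), stress = integer(n_rec),
      motivation = integer(n_rec), availability = integer(n_rec),
      interacting_smoker = logical(n_rec), alcohol_past_hour = logical(n_rec)
    )
    for (k in unique(cls)) {
      sel <- cls == k
      items[sel, ] <- draw_items(sum(sel), prev_of[[k]], cfg$latent_correlation)
    }

    if (inconsistent[i]) {
      class_counts["EXCLUDED_INCONSISTENT"] <- class_counts["EXCLUDED_INCONSISTENT"] + n_rec
    } else {
      tab <- table(cls)
      class_counts[names(tab)] <- class_counts[names(tab)] + as.integer(tab)
    }

    records[[i]] <- tibble::tibble(
      participant_id = ids[i],
      timestamp = origin + times * 60,
      prompt_type = types,
      urge = as.integer(items$urge),
      stress = as.integer(items$stress),
      motivation = as.integer(items$motivation),
      availability = as.integer(items$availability),
      interacting_smoker = items$interacting_smoker,
      alcohol_past_hour = items$alcohol_past_hour,
      smoked_since_last = if (is_lapser[i]) times >= lapse_min else rep(FALSE, n_rec)
    )
  }

  cohort <- ema_cohort(dplyr::bind_rows(participants), dplyr::bind_rows(records))
  attr(cohort, "class_counts") <- class_counts
  cohort
}
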