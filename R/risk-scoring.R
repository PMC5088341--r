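#' Dichotomize the six momentary items into lapse-risk indicators
#'
#' Applies the study's scoring rule to map each EMA's responses onto six
#' binary risk factors: agreeing or strongly agreeing to urge and stress
#' (response 4 or 5), disagreeing or strongly disagreeing with commitment
#' to being smoke free (motivation 1 or 2), cigarettes fairly easily or
#' easily available (availability 4 or 5), and the two yes/no items passed
#' through.
#'
#' @param urge,stress,motivation,availability Integer vectors in 1-5.
#' @param interacting_smoker,alcohol_past_hour Logical vectors.
#' @return A tibble with logical columns `urge_high`, `stress_high`,
#'   `motivation_low`, `cigs_available`, `interacting_smoker`,
#'   `alcohol_recent`.
#' @export
#' @examples
#' dichotomize(5, 2, 5, 4, FALSE, FALSE)
dichotomize <- function(urge, stress, motivation, availability,
                        interacting_smoker, alcohol_past_hour) {
  tibble::tibble(
    urge_high = urge >= 4L,
    stress_high = stress >= 4L,
    motivation_low = motivation <= 2L,
    cigs_available = availability >= 4L,
    interacting_smoker = as.logical(interacting_smoker),
    alcohol_recent = as.logical(alcohol_past_hour)
  )
}

#' Unweighted lapse-risk score: count of risk factors present
#'
#' One point per positive indicator, so the score ranges 0-6.
#'
#' @param indicators A tibble/data frame of the six logical indicator
#'   columns as returned by [dichotomize()].
#' @return Integer vector in 0-6.
#' @export
unweighted_score <- function(indicators) {
  as.integer(rowSums(as.matrix(indicators[, RISK_FACTORS, drop = FALSE])))
}

#' Weights defining the linear lapse-risk score
#'
#' The weighted estimator centers each ordinal item at `offset` (3 =
#' neutral / "with difficulty") and combines the terms linearly; the two
#' binary items enter as 0/1, and motivation enters with a minus sign
#' (commitment is protective). The defaults reproduce the study's final
#' estimator:
#' `(urge - 3) * 0.2 + (stress - 3) * 0.2 + (availability - 3) * 0.7 +`
#' `interacting_smoker + alcohol + (motivation - 3) * (-0.2)`.
#'
#' @param offset Ordinal centering constant.
#' @param w_urge,w_stress,w_motivation,w_availability Coefficients on the
#'   centered ordinal items (motivation's applies with a minus sign).
#' @param w_smoker_present,w_alcohol Coefficients on the binary items.
#' @return A list of class `risk_weights`.
#' @export
risk_weights <- function(offset = 3,
                         w_urge = 0.2, w_stress = 0.2, w_motivation = 0.2,
                         w_availability = 0.7,
                         w_smoker_present = 1, w_alcohol = 1) {
  w <- list(
    offset = offset, w_urge = w_urge, w_stress = w_stress,
    w_motivation = w_motivation, w_availability = w_availability,
    w_smoker_present = w_smoker_present, w_alcohol = w_alcohol
  )
  if (!all(vapply(w, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), logical(1)))) {
    validation_abort("all weights must be single finite numbers")
  }
  structure(w, class = "risk_weights")
}

#' @export
print.risk_weights <- function(x, ...) {
  cat(sprintf(
    "<risk_weights> (urge-%s)*%s + (stress-%s)*%s + (availability-%s)*%s + %s*smoker + %s*alcohol - (motivation-%s)*%s\n",
    x$offset, x$w_urge, x$offset, x$w_stress, x$offset, x$w_availability,
    x$w_smoker_present, x$w_alcohol, x$offset, x$w_motivation
  ))
  invisible(x)
}

#' Weighted lapse-risk score
#'
#' Evaluates the linear risk score on raw item responses. With the default
#' weights the achievable range over all response profiles is -2.6 to 4.6
#' (by exhaustive enumeration of the 5^4 x 2^2 profiles).
#'
#' @inheritParams dichotomize
#' @param weights A [risk_weights()].
#' @return Numeric vector of scores.
#' @export
#' @examples
#' weighted_score(3, 3, 3, 3, FALSE, FALSE) # neutral profile -> 0
#' weighted_score(1, 1, 5, 1, FALSE, FALSE) # minimum-risk profile -> -2.6
weighted_score <- function(urge, stress, motivation, availability,
                           interacting_smoker, alcohol_past_hour,
                           weights = risk_weights()) {
  w <- weights
  w$w_urge * (urge - w$offset) +
    w$w_stress * (stress - w$offset) +
    w$w_availability * (availability - w$offset) +
    w$w_smoker_present * as.numeric(interacting_smoker) +
    w$w_alcohol * as.numeric(alcohol_past_hour) -
    w$w_motivation * (motivation - w$offset)
}

#' Score a labeled analysis set
#'
#' Appends the six risk indicators, the unweighted count score
#' (`n_risk_factors`) and, when weights are supplied, the weighted score
#' (`weighted_risk_score`) to every record; row order is preserved.
#' Records missing any of the six items are dropped with a message giving
#' the count.
#'
#' @param records Labeled records from [build_analysis_set()] (any tibble
#'   with the six item columns works).
#' @param weights A [risk_weights()], or `NULL` to skip the weighted score.
#' @return The input tibble with indicator and score columns appended.
#' @export
score_analysis_set <- function(records, weights = risk_weights()) {
  item_cols <- c(
    "urge", "stress", "motivation", "availability",
    "interacting_smoker", "alcohol_past_hour"
  )
  complete <- stats::complete.cases(records[, item_cols])
  if (!all(complete)) {
    inform(sprintf(
      "dropping %d record(s) with missing risk items", sum(!complete)
    ))
    records <- records[complete, ]
  }
  ind <- dichotomize(
    records$urge, records$stress, records$motivation, records$availability,
    records$interacting_smoker, records$alcohol_past_hour
  )
  out <- dplyr::bind_cols(records, ind[, setdiff(RISK_FACTORS, names(records))])
  out$n_risk_factors <- unweighted_score(ind)
  if (!is.null(weights)) {
    out$weighted_risk_score <- weighted_score(
      records$urge, records$stress, records$motivation, records$availability,
      records$interacting_smoker, records$alcohol_past_hour, weights
    )
  }
  out
}

#' Exact distribution of the risk-factor count under independence
#'
#' Poisson-binomial probability mass function of the number of positive
#' indicators when the six risk factors are independent Bernoulli draws
#' with the given prevalences — the exact oracle for count-score tail
#' probabilities (e.g. the share of imminent-lapse EMAs reaching a given
#' cut-off).
#'
#' @param prevalence Numeric vector of indicator probabilities in `[0, 1]`.
#' @return Named numeric vector: `P(count = 0), ..., P(count = k)`.
#' @export
#' @examples
#' pmf <- risk_count_pmf(c(0.593, 0.411, 0.173, 0.748, 0.336, 0.191))
#' sum(pmf[as.character(3:6)]) # P(count >= 3)
risk_count_pmf <- function(prevalence) {
  if (any(is.na(prevalence) | prevalence < 0 | prevalence > 1)) {
    validation_abort("prevalences must lie in [0, 1]")
  }
  pmf <- 1
  for (p in prevalence) {
    k <- length(pmf)
    pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  }
  names(pmf) <- 0:(length(pmf) - 1L)
  pmf
}
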