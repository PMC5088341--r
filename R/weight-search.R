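#' Configuration for the weight grid search
#'
#' The search space is the Cartesian product of candidate coefficients for
#' the four centered ordinal items and the two binary items. The default
#' ordinal grid is 0.0 to 1.0 in steps of 0.1 and the default binary grid
#' is \{0, 0.5, 1\}, giving 11^4 x 3^2 = 131,769 weight vectors. The
#' objective is either the best Youden index (sensitivity + specificity -
#' 1) over candidate cut-offs, or the AUC of the weighted score.
#'
#' @param weight_grid_ordinal Candidate coefficients for urge, stress,
#'   motivation and availability (motivation always enters negatively, so
#'   candidates are constrained non-negative).
#' @param weight_grid_binary Candidates for the two binary items.
#' @param objective `"youden_max_over_cutoffs"` or `"auc"`.
#' @param cutoff_grid Candidate cut-offs; `NULL` (default) uses all
#'   midpoints between adjacent observed score values, which is exhaustive
#'   for the Youden objective.
#' @return A list of class `search_config`.
#' @export
search_config <- function(weight_grid_ordinal = seq(0, 1, by = 0.1),
                          weight_grid_binary = c(0, 0.5, 1),
                          objective = c("youden_max_over_cutoffs", "auc"),
                          cutoff_grid = NULL) {
  objective <- match.arg(objective)
  if (length(weight_grid_ordinal) == 0L || length(weight_grid_binary) == 0L) {
    validation_abort("weight grids must be non-empty")
  }
  if (any(!is.finite(weight_grid_ordinal)) || any(!is.finite(weight_grid_binary))) {
    validation_abort("weight grids must be finite")
  }
  if (any(weight_grid_ordinal < 0)) {
    validation_abort("ordinal weight candidates must be non-negative (motivation enters with a fixed minus sign)")
  }
  structure(
    list(
      weight_grid_ordinal = sort(unique(weight_grid_ordinal)),
      weight_grid_binary = sort(unique(weight_grid_binary)),
      objective = objective,
      cutoff_grid = cutoff_grid
    ),
    class = "search_config"
  )
}

# design matrix whose inner product with (w_urge, w_stress, w_motivation,
# w_availability, w_smoker, w_alcohol) is the weighted score; motivation's
# column carries the minus sign
score_design <- function(records, offset = 3) {
  cbind(
    urge = records$urge - offset,
    stress = records$stress - offset,
    motivation = -(records$motivation - offset),
    availability = records$availability - offset,
    smoker = as.numeric(records$interacting_smoker),
    alcohol = as.numeric(records$alcohol_past_hour)
  )
}

weights_from_vector <- function(w, offset = 3) {
  w <- unname(w)
  risk_weights(
    offset = offset,
    w_urge = w[1], w_stress = w[2], w_motivation = w[3],
    w_availability = w[4], w_smoker_present = w[5], w_alcohol = w[6]
  )
}

#' Sensitivity and specificity of a weighted estimator at a cut-off
#'
#' Sensitivity is the fraction of imminent-lapse (`WITHIN_4H`) records
#' whose weighted score exceeds the cut-off; specificity is the fraction
#' of all other retained records at or below it. The strict convention
#' "score > cutoff flags" is used throughout; to reproduce a
#' greater-or-equal cut-off `c` (e.g. "3 or more risk factors"), pass any
#' cut-off just below `c` such as `c - 0.5` on the integer count score.
#'
#' @param records Labeled records (from [build_analysis_set()]) with the
#'   raw item columns.
#' @param weights A [risk_weights()].
#' @param cutoff Scalar cut-off.
#' @return Named numeric vector `c(sensitivity = , specificity = )`.
#' @export
evaluate_weights <- function(records, weights, cutoff) {
  pos <- records$proximity_label == "WITHIN_4H"
  if (!any(pos) || all(pos)) {
    validation_abort("records must contain both imminent-lapse and comparison classes")
  }
  s <- weighted_score(
    records$urge, records$stress, records$motivation, records$availability,
    records$interacting_smoker, records$alcohol_past_hour, weights
  )
  c(
    sensitivity = mean(s[pos] > cutoff),
    specificity = mean(s[!pos] <= cutoff)
  )
}

# best Youden over all cut-offs for a score vector over aggregated profiles;
# returns c(J, cutoff). Cut-offs considered are midpoints between adjacent
# distinct scores (plus one below the minimum / above the maximum).
best_youden <- function(scores, n_pos, n_neg, cutoff_grid = NULL) {
  P <- sum(n_pos)
  N <- sum(n_neg)
  if (!is.null(cutoff_grid)) {
    J <- vapply(cutoff_grid, function(cut) {
      sum(n_pos[scores > cut]) / P + sum(n_neg[scores <= cut]) / N - 1
    }, numeric(1))
    i <- which.max(J)
    return(c(J = J[i], cutoff = cutoff_grid[i]))
  }
  ord <- order(scores)
  s <- scores[ord]
  cp <- cumsum(n_pos[ord]) # positives at or below each score
  cn <- cumsum(n_neg[ord])
  keep <- c(diff(s) > 1e-12, TRUE) # collapse tied scores
  s <- s[keep]
  cp <- cp[keep]
  cn <- cn[keep]
  # cutting just above s[i]: specificity cn[i]/N, sensitivity 1 - cp[i]/P;
  # prepend the cut below every score (sens 1, spec 0)
  J <- c(0, (1 - cp / P) + cn / N - 1)
  cuts <- c(s[1] - 1, (c(s[-1], s[length(s)] + 2) + s) / 2)
  i <- which.max(J)
  c(J = J[i], cutoff = cuts[i])
}

#' Exhaustive grid search for risk-factor weights
#'
#' Evaluates every weight vector on the Cartesian grid and returns the one
#' maximizing the objective: for `youden_max_over_cutoffs`, each vector's
#' value is the maximum of sensitivity + specificity - 1 over candidate
#' cut-offs; for `auc`, the rank-based AUC of the weighted score. Ties are
#' broken deterministically by smallest L1 norm, then lexicographic order
#' of the coefficient tuple (urge, stress, motivation, availability,
#' smoker, alcohol).
#'
#' Internally the records are collapsed to unique response profiles with
#' class counts, so the cost per weight vector is proportional to the
#' number of distinct profiles (at most 2,500), not the record count.
#'
#' @param records Labeled records containing both a `WITHIN_4H` class and
#'   at least one other retained class.
#' @param config A [search_config()].
#' @return A list of class `search_result`: `best_weights`
#'   ([risk_weights()]), `best_cutoff`, `objective_value`, `objective`,
#'   `n_evaluated`, and a `trace` tibble of the per-vector objective
#'   values.
#' @export
grid_search <- function(records, config = search_config()) {
  pos <- records$proximity_label == "WITHIN_4H"
  if (!any(pos) || all(pos)) {
    validation_abort("grid search needs both imminent-lapse and comparison records")
  }
  X <- score_design(records)
  # aggregate identical response profiles
  key <- apply(X, 1, paste, collapse = ",")
  grp <- match(key, unique(key))
  Xp <- X[!duplicated(grp), , drop = FALSE]
  n_pos <- as.vector(tapply(as.numeric(pos), grp, sum))
  n_neg <- as.vector(tapply(as.numeric(!pos), grp, sum))

  g_o <- config$weight_grid_ordinal
  g_b <- config$weight_grid_binary
  grid <- as.matrix(expand.grid(
    urge = g_o, stress = g_o, motivation = g_o, availability = g_o,
    smoker = g_b, alcohol = g_b, KEEP.OUT.ATTRS = FALSE
  ))
  n_grid <- nrow(grid)

  obj <- numeric(n_grid)
  cut <- numeric(n_grid)
  chunk <- 4000L
  for (start in seq(1L, n_grid, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_grid)
    S <- Xp %*% t(grid[idx, , drop = FALSE]) # profiles x chunk scores
    if (config$objective == "youden_max_over_cutoffs") {
      for (j in seq_along(idx)) {
        bj <- best_youden(S[, j], n_pos, n_neg, config$cutoff_grid)
        obj[idx[j]] <- bj[["J"]]
        cut[idx[j]] <- bj[["cutoff"]]
      }
    } else {
      for (j in seq_along(idx)) {
        obj[idx[j]] <- auc_weighted_counts(S[, j], n_pos, n_neg)
        cut[idx[j]] <- NA_real_
      }
    }
  }

  # maximize objective; ties -> smallest L1 norm -> lexicographic tuple
  l1 <- rowSums(abs(grid))
  best <- order(
    -obj, l1, grid[, 1], grid[, 2], grid[, 3], grid[, 4], grid[, 5], grid[, 6]
  )[1]

  structure(
    list(
      best_weights = weights_from_vector(grid[best, ]),
      best_cutoff = cut[best],
      objective_value = obj[best],
      objective = config$objective,
      n_evaluated = n_grid,
      trace = tibble::tibble(
        w_urge = grid[, 1], w_stress = grid[, 2], w_motivation = grid[, 3],
        w_availability = grid[, 4], w_smoker_present = grid[, 5],
        w_alcohol = grid[, 6], objective_value = obj, best_cutoff = cut
      )
    ),
    class = "search_result"
  )
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf(
    "<search_result> objective %s = %.4f over %d weight vectors; cutoff %.3f\n",
    x$objective, x$objective_value, x$n_evaluated,
    if (is.na(x$best_cutoff)) NA else x$best_cutoff
  ))
  print(x$best_weights)
  invisible(x)
}

# rank AUC from aggregated score counts (ties count 1/2)
auc_weighted_counts <- function(scores, n_pos, n_neg) {
  ord <- order(scores)
  s <- scores[ord]
  g <- cumsum(c(TRUE, diff(s) > 1e-12)) # collapse tied scores across profiles
  np <- as.vector(tapply(n_pos[ord], g, sum))
  nn <- as.vector(tapply(n_neg[ord], g, sum))
  cum_neg <- cumsum(nn) - nn # negatives strictly below each score value
  sum(np * (cum_neg + 0.5 * nn)) / (sum(np) * sum(nn))
}
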