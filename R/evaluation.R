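#' Risk-factor prevalence by proximity class
#'
#' Replicates the study's descriptive table: for each proximity class
#' present in the data, the percentage of EMAs endorsing each of the six
#' risk factors and the mean (and SD) of the risk-factor count. Classes
#' with no records are absent from the output, not reported as zero.
#'
#' @param scored Scored, labeled records from [score_analysis_set()].
#' @return A tibble: one row per (class, measure), with columns
#'   `proximity_label`, `measure`, `value`, `n`.
#' @export
prevalence_table <- function(scored) {
  present <- scored[!is.na(scored$proximity_label), ]
  out <- lapply(split(present, droplevels(present$proximity_label)), function(d) {
    tibble::tibble(
      proximity_label = as.character(d$proximity_label[1]),
      measure = c(RISK_FACTORS, "mean_risk_factors", "sd_risk_factors"),
      value = unname(c(
        vapply(RISK_FACTORS, function(f) 100 * mean(d[[f]]), numeric(1)),
        mean(d$n_risk_factors),
        stats::sd(d$n_risk_factors)
      )),
      n = nrow(d)
    )
  })
  dplyr::bind_rows(out)
}

#' Rank-based AUC (Mann-Whitney formulation)
#'
#' Concordance probability that a randomly chosen positive outscores a
#' randomly chosen negative, with ties counted one half — identical to the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) class labels, `TRUE` = positive.
#' @return The AUC.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    validation_abort("both classes must be present to compute an AUC")
  }
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Empirical ROC curve
#'
#' One operating point per distinct score value: at threshold t the
#' positive rate is computed with the strict convention `score > t`.
#' Includes the (0, 0) and (1, 1) endpoints.
#'
#' @inheritParams auc_rank
#' @return A tibble of class `roc_curve`: `threshold` (decreasing from
#'   `Inf`), `tpr`, `fpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    validation_abort("both classes must be present to compute an ROC curve")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores[labels] > t), numeric(1)) / n_pos
  fpr <- vapply(thr, function(t) sum(scores[!labels] > t), numeric(1)) / n_neg
  out <- tibble::tibble(
    threshold = c(Inf, thr, -Inf),
    tpr = c(0, tpr, 1),
    fpr = c(0, fpr, 1)
  )
  class(out) <- c("roc_curve", class(out))
  out
}

#' ROC curve and AUC with a 95% confidence interval
#'
#' The AUC point estimate is the rank (Mann-Whitney) statistic with ties
#' counted one half; the confidence interval comes from the asymptotic
#' variance of the rank statistic (DeLong). The AUC equals the trapezoidal
#' area under the returned curve.
#'
#' @inheritParams auc_rank
#' @param conf_level Confidence level (default 0.95).
#' @return A list: `roc` ([roc_curve()]), `auc`, `ci` (length-2 vector).
#' @export
roc_and_auc <- function(scores, labels, conf_level = 0.95) {
  labels <- as.logical(labels)
  curve <- roc_curve(scores, labels)
  auc <- auc_rank(scores, labels)
  suppressMessages(
    r <- pROC::roc(response = labels, predictor = scores, direction = "<", quiet = TRUE)
  )
  ci <- as.numeric(pROC::ci.auc(r, conf.level = conf_level, method = "delong"))[c(1, 3)]
  list(roc = curve, auc = auc, ci = ci)
}

#' Compare two correlated AUCs on the same records
#'
#' Paired comparison of two scoring rules evaluated on the same EMAs, via
#' the DeLong structural-components method; a seeded paired-bootstrap
#' alternative (resampling records with replacement and recomputing the
#' AUC difference) is also available.
#'
#' @param scores_a,scores_b Two score vectors on the same records.
#' @inheritParams auc_rank
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @return A list: `auc_a`, `auc_b`, `p_value`, `method`.
#' @export
compare_auc <- function(scores_a, scores_b, labels,
                        method = c("delong", "bootstrap"),
                        n_boot = 2000L, seed = 1L) {
  method <- match.arg(method)
  labels <- as.logical(labels)
  auc_a <- auc_rank(scores_a, labels)
  auc_b <- auc_rank(scores_b, labels)
  if (isTRUE(all.equal(scores_a, scores_b))) {
    return(list(auc_a = auc_a, auc_b = auc_b, p_value = 1, method = method))
  }
  if (method == "delong") {
    suppressMessages({
      ra <- pROC::roc(response = labels, predictor = scores_a, direction = "<", quiet = TRUE)
      rb <- pROC::roc(response = labels, predictor = scores_b, direction = "<", quiet = TRUE)
      p <- pROC::roc.test(ra, rb, paired = TRUE, method = "delong")$p.value
    })
    # identical rank orderings give a zero-variance difference; p is then 1
    if (is.nan(p)) p <- 1
  } else {
    set.seed(seed)
    n <- length(labels)
    diffs <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (!any(labels[idx]) || all(labels[idx])) {
        return(NA_real_)
      }
      auc_rank(scores_a[idx], labels[idx]) - auc_rank(scores_b[idx], labels[idx])
    }, numeric(1))
    diffs <- diffs[!is.na(diffs)]
    p <- min(1, 2 * min(mean(diffs <= 0), mean(diffs >= 0)))
  }
  list(auc_a = auc_a, auc_b = auc_b, p_value = p, method = method)
}

#' Participant-level detection rate
#'
#' Fraction of lapsers with at least one imminent-lapse (`WITHIN_4H`) EMA
#' whose score exceeds the cut-off — the study's person-level measure of
#' whether the estimator would have fired in time at least once.
#'
#' @param scored Scored, labeled records from [score_analysis_set()].
#' @param roster Participant roster tibble (needs `participant_id`,
#'   `first_lapse_time`, `consistent_reporting`).
#' @param cutoff Scalar cut-off; strict convention `score > cutoff`.
#' @param score_col Which score column to threshold
#'   (`"n_risk_factors"` or `"weighted_risk_score"`).
#' @return The detection proportion; attribute `"n_lapsers"` carries the
#'   denominator.
#' @export
participant_detection <- function(scored, roster, cutoff,
                                  score_col = "weighted_risk_score") {
  lapsers <- roster$participant_id[
    !is.na(roster$first_lapse_time) & roster$consistent_reporting
  ]
  if (length(lapsers) == 0L) {
    validation_abort("no lapsers in the roster")
  }
  flagged <- scored$participant_id[
    scored$proximity_label == "WITHIN_4H" & scored[[score_col]] > cutoff
  ]
  out <- mean(lapsers %in% flagged)
  attr(out, "n_lapsers") <- length(lapsers)
  out
}

#' Full evaluation report for a scored analysis set
#'
#' Bundles the study's evaluation outputs: the prevalence table, operating
#' points of the unweighted (cut-off: 3 or more factors) and weighted
#' (cut-off 1.0) estimators, participant-level detection for both, ROC
#' curves and AUCs with confidence intervals for both scores, the
#' correlated-AUC comparison, and mixed-effects group comparisons.
#'
#' @param scored Scored, labeled records.
#' @param roster Participant roster tibble.
#' @param unweighted_cutoff Count cut-off `c` flagging `>= c` factors
#'   (default 3; applied as strict threshold `c - 0.5`).
#' @param weighted_cutoff Weighted-score cut-off (default 1.0, strict).
#' @param group_tests Run [group_compare()] (slowest component).
#' @param seed Seed forwarded to stochastic subprocedures.
#' @return A list of class `lapse_eval_report`.
#' @export
eval_report <- function(scored, roster, unweighted_cutoff = 3,
                        weighted_cutoff = 1.0, group_tests = TRUE, seed = 1L) {
  pos <- scored$proximity_label == "WITHIN_4H"
  labels <- pos
  uw <- scored$n_risk_factors
  wt <- scored$weighted_risk_score
  strict_uw <- unweighted_cutoff - 0.5

  op <- function(scores, cutoff) {
    c(
      cutoff = cutoff,
      sensitivity = mean(scores[pos] > cutoff),
      specificity = mean(scores[!pos] <= cutoff)
    )
  }
  auc_uw <- roc_and_auc(uw, labels)
  auc_wt <- roc_and_auc(wt, labels)
  cmp <- compare_auc(wt, uw, labels, method = "delong")

  report <- list(
    n_records = nrow(scored),
    n_within = sum(pos),
    prevalence = prevalence_table(scored),
    operating_points = list(
      unweighted = op(uw, strict_uw),
      weighted = op(wt, weighted_cutoff)
    ),
    participant_detection = c(
      unweighted = as.numeric(
        participant_detection(scored, roster, strict_uw, "n_risk_factors")
      ),
      weighted = as.numeric(
        participant_detection(scored, roster, weighted_cutoff, "weighted_risk_score")
      )
    ),
    auc_unweighted = auc_uw[c("auc", "ci")],
    auc_weighted = auc_wt[c("auc", "ci")],
    auc_comparison = cmp,
    roc = list(unweighted = auc_uw$roc, weighted = auc_wt$roc),
    group_tests = if (group_tests) group_compare(scored, roster, seed = seed) else NULL
  )
  class(report) <- "lapse_eval_report"
  report
}

#' @export
print.lapse_eval_report <- function(x, ...) {
  cat(sprintf(
    "<lapse_eval_report> %d records (%d imminent-lapse)\n", x$n_records, x$n_within
  ))
  ou <- x$operating_points$unweighted
  ow <- x$operating_points$weighted
  cat(sprintf(
    "  unweighted: sens %.1f%% / spec %.1f%% (cutoff %.1f); AUC %.2f (%.2f-%.2f)\n",
    100 * ou["sensitivity"], 100 * ou["specificity"], ou["cutoff"],
    x$auc_unweighted$auc, x$auc_unweighted$ci[1], x$auc_unweighted$ci[2]
  ))
  cat(sprintf(
    "  weighted:   sens %.1f%% / spec %.1f%% (cutoff %.1f); AUC %.2f (%.2f-%.2f)\n",
    100 * ow["sensitivity"], 100 * ow["specificity"], ow["cutoff"],
    x$auc_weighted$auc, x$auc_weighted$ci[1], x$auc_weighted$ci[2]
  ))
  cat(sprintf(
    "  AUC comparison (weighted vs unweighted, %s): p = %.4g\n",
    x$auc_comparison$method, x$auc_comparison$p_value
  ))
  cat(sprintf(
    "  participant detection: unweighted %.0f%%, weighted %.0f%%\n",
    100 * x$participant_detection["unweighted"],
    100 * x$participant_detection["weighted"]
  ))
  invisible(x)
}
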