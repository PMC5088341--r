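test_that("the prevalence table reproduces raw tallies exactly", {
  d <- random_labeled_records(200, seed = 41)
  scored <- score_analysis_set(d)
  tab <- prevalence_table(scored)
  for (cls in unique(as.character(scored$proximity_label))) {
    sub <- scored[scored$proximity_label == cls, ]
    for (f in c("urge_high", "cigs_available", "alcohol_recent")) {
      got <- tab$value[tab$proximity_label == cls & tab$measure == f]
      expect_equal(got, 100 * mean(sub[[f]]))
    }
    expect_equal(
      tab$value[tab$proximity_label == cls & tab$measure == "mean_risk_factors"],
      mean(sub$n_risk_factors)
    )
  }
  # an absent class is absent, not reported as zero
  expect_false("PRE_LAPSE_OVER_4H" %in% tab$proximity_label)

  # degenerate one-record class
  one <- score_analysis_set(random_labeled_records(1, seed = 1, p_within = 1))
  t1 <- prevalence_table(one)
  expect_equal(
    t1$value[t1$measure == "mean_risk_factors"],
    one$n_risk_factors[1]
  )
})

test_that("rank AUC equals the pairwise oracle and the trapezoidal ROC area", {
  # trivial cases
  expect_equal(auc_rank(c(1, 2, 3), c(0, 0, 1)), 1)
  expect_equal(auc_rank(rep(2, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc_rank(1:3, c(1, 1, 1)), class = "emalapse_validation_error")

  for (seed in c(3, 71)) {
    set.seed(seed)
    n <- 500
    labels <- runif(n) < 0.3
    scores <- round(rnorm(n, mean = labels), 1) # rounding induces ties
    a <- auc_rank(scores, labels)
    expect_equal(a, auc_pairwise_oracle(scores, labels), tolerance = 1e-12)
    curve <- roc_curve(scores, labels)
    expect_equal(a, trapezoid_area(curve), tolerance = 1e-9)
    # curve invariants: endpoints and monotonicity as the threshold falls
    expect_equal(curve$tpr[1], 0)
    expect_equal(curve$fpr[1], 0)
    expect_equal(curve$tpr[nrow(curve)], 1)
    expect_equal(curve$fpr[nrow(curve)], 1)
    expect_true(all(diff(curve$tpr) >= 0))
    expect_true(all(diff(curve$fpr) >= 0))
  }
})

test_that("the AUC confidence interval brackets the point estimate", {
  set.seed(11)
  labels <- runif(400) < 0.25
  scores <- rnorm(400, mean = labels)
  res <- roc_and_auc(scores, labels)
  expect_lte(res$ci[1], res$auc)
  expect_gte(res$ci[2], res$auc)
  expect_equal(res$auc, trapezoid_area(res$roc), tolerance = 1e-9)
})

test_that("operating points read off the ROC match evaluate_weights", {
  d <- random_labeled_records(500, seed = 19)
  scored <- score_analysis_set(d)
  pos <- scored$proximity_label == "WITHIN_4H"
  curve <- roc_curve(scored$weighted_risk_score, pos)
  for (thr in curve$threshold[c(3, 7)]) {
    op <- evaluate_weights(d, risk_weights(), thr)
    row <- which(curve$threshold == thr)
    expect_equal(unname(op["sensitivity"]), curve$tpr[row])
    expect_equal(1 - unname(op["specificity"]), curve$fpr[row])
  }
})

test_that("correlated-AUC comparison handles identity, shifts and real differences", {
  set.seed(29)
  labels <- runif(500) < 0.3
  a <- rnorm(500, mean = labels)
  expect_equal(compare_auc(a, a, labels)$p_value, 1)
  # a constant shift never changes ranks, so AUCs and the p-value agree
  shifted <- compare_auc(a, a + 5, labels)
  expect_equal(shifted$auc_a, shifted$auc_b)
  expect_equal(shifted$p_value, 1)

  b <- a + rnorm(500, sd = 0.8) # degraded copy
  dl <- compare_auc(a, b, labels, method = "delong")
  bs <- compare_auc(a, b, labels, method = "bootstrap", n_boot = 2000, seed = 77)
  expect_equal(dl$auc_a, bs$auc_a)
  expect_lt(abs(dl$p_value - bs$p_value), 0.02) # method cross-check
})

test_that("participant detection counts lapsers with a flagged imminent EMA", {
  roster <- make_roster(
    c("l1", "l2", "a1"),
    c("2011-08-02 12:00", "2011-08-03 12:00", NA)
  )
  scored <- tibble::tibble(
    participant_id = c("l1", "l1", "l2", "a1"),
    proximity_label = factor(
      c("WITHIN_4H", "PRE_LAPSE_OVER_4H", "WITHIN_4H", "ABSTAINER"),
      levels = c("WITHIN_4H", "PRE_LAPSE_OVER_4H", "ABSTAINER")
    ),
    n_risk_factors = c(4L, 5L, 1L, 6L),
    weighted_risk_score = c(2.1, 3.0, 0.2, 4.0)
  )
  # only l1 has an imminent EMA above the cut-off (l2's is 0.2; a1 is no lapser)
  expect_equal(as.numeric(
    participant_detection(scored, roster, 1.0, "weighted_risk_score")
  ), 0.5)
  expect_equal(as.numeric(
    participant_detection(scored, roster, 2.5, "n_risk_factors")
  ), 0.5)
  # cut-off below all scores flags every lapser with an imminent EMA
  expect_equal(as.numeric(
    participant_detection(scored, roster, -10, "weighted_risk_score")
  ), 1.0)
  expect_error(
    participant_detection(scored, make_roster("a1"), 1.0),
    class = "emalapse_validation_error"
  )
})

test_that("participant detection agrees with a direct per-participant scan", {
  for (seed in 1:10) {
    cohort <- generate_cohort(sim_config(
      n_lapsers = 8L, n_abstainers = 4L, master_seed = 500L + seed
    ))
    scored <- score_analysis_set(suppressMessages(build_analysis_set(cohort)))
    got <- as.numeric(participant_detection(
      scored, cohort$participants, 1.0, "weighted_risk_score"
    ))
    # oracle: loop over lapsers, scan their imminent records
    lapsers <- cohort$participants$participant_id[cohort$participants$lapsed]
    hits <- 0
    for (id in lapsers) {
      sub <- scored[scored$participant_id == id &
        scored$proximity_label == "WITHIN_4H", ]
      if (nrow(sub) > 0 && any(sub$weighted_risk_score > 1.0)) hits <- hits + 1
    }
    expect_equal(got, hits / length(lapsers))
  }
})

test_that("the evaluation report assembles consistent pieces", {
  cohort <- generate_cohort(sim_config(n_lapsers = 25L, n_abstainers = 20L, master_seed = 61L))
  scored <- score_analysis_set(suppressMessages(build_analysis_set(cohort)))
  rep <- eval_report(scored, cohort$participants, group_tests = FALSE)
  expect_s3_class(rep, "lapse_eval_report")
  pos <- scored$proximity_label == "WITHIN_4H"
  expect_equal(rep$n_within, sum(pos))
  # operating point recomputation
  op <- rep$operating_points$unweighted
  expect_equal(unname(op["sensitivity"]), mean(scored$n_risk_factors[pos] >= 3))
  expect_equal(unname(op["specificity"]), mean(scored$n_risk_factors[!pos] < 3))
  # AUC pieces agree with direct recomputation
  expect_equal(rep$auc_weighted$auc, auc_rank(scored$weighted_risk_score, pos))
  expect_equal(rep$auc_unweighted$auc, auc_rank(scored$n_risk_factors, pos))
  expect_true(rep$auc_comparison$p_value >= 0 && rep$auc_comparison$p_value <= 1)
  expect_output(print(rep), "AUC")
})
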