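test_that("dichotomization applies the study's scoring rule", {
  expect_equal(
    unlist(dichotomize(5, 2, 5, 4, FALSE, FALSE)),
    c(
      urge_high = TRUE, stress_high = FALSE, motivation_low = FALSE,
      cigs_available = TRUE, interacting_smoker = FALSE, alcohol_recent = FALSE
    )
  )
  # the neutral midpoint endorses nothing
  expect_false(any(unlist(dichotomize(3, 3, 3, 3, FALSE, FALSE))))
  # the maximum-risk profile endorses all six factors
  expect_true(all(unlist(dichotomize(5, 5, 1, 5, TRUE, TRUE))))
  # category boundaries: 4 endorses agree-keyed items, 2 endorses low motivation
  expect_equal(
    unweighted_score(dichotomize(4, 4, 2, 4, FALSE, FALSE)), 4L
  )
  expect_equal(
    unweighted_score(dichotomize(3, 3, 3, 3, TRUE, FALSE)), 1L
  )
})

test_that("exhaustive enumeration reproduces both scores' ranges and consistency", {
  prof <- all_profiles()
  ind <- dichotomize(
    prof$urge, prof$stress, prof$motivation, prof$availability,
    prof$interacting_smoker, prof$alcohol_past_hour
  )
  counts <- unweighted_score(ind)
  expect_true(all(counts %in% 0:6))
  expect_equal(range(counts), c(0L, 6L))
  # count score is the all-ones weighting of the indicator vector
  expect_equal(counts, as.integer(as.matrix(ind) %*% rep(1, 6)))

  w <- weighted_score(
    prof$urge, prof$stress, prof$motivation, prof$availability,
    prof$interacting_smoker, prof$alcohol_past_hour
  )
  expect_equal(min(w), -2.6)
  expect_equal(max(w), 4.6)
  # spot values: neutral profile scores zero; extreme profiles hit the bounds
  expect_equal(weighted_score(3, 3, 3, 3, FALSE, FALSE), 0)
  expect_equal(weighted_score(1, 1, 5, 1, FALSE, FALSE), -2.6)
  expect_equal(weighted_score(5, 5, 1, 5, TRUE, TRUE), 4.6)
})

test_that("both scores are monotone in every single-item perturbation", {
  prof <- all_profiles()
  score_both <- function(p) {
    list(
      uw = unweighted_score(dichotomize(
        p$urge, p$stress, p$motivation, p$availability,
        p$interacting_smoker, p$alcohol_past_hour
      )),
      wt = weighted_score(
        p$urge, p$stress, p$motivation, p$availability,
        p$interacting_smoker, p$alcohol_past_hour
      )
    )
  }
  base <- score_both(prof)
  bump <- function(col, delta) {
    p <- prof
    p[[col]] <- pmin(pmax(p[[col]] + delta, 1L), 5L)
    p
  }
  for (col in c("urge", "stress", "availability")) {
    up <- score_both(bump(col, 1L))
    expect_true(all(up$uw >= base$uw))
    expect_true(all(up$wt >= base$wt))
  }
  up <- score_both(bump("motivation", 1L)) # more commitment is protective
  expect_true(all(up$uw <= base$uw))
  expect_true(all(up$wt <= base$wt))
  # flipping a binary on raises the weighted score by exactly its coefficient
  on <- prof
  on$interacting_smoker <- TRUE
  delta <- score_both(on)$wt - base$wt
  expect_true(all(abs(delta[!prof$interacting_smoker] - 1) < 1e-12))
  on <- prof
  on$alcohol_past_hour <- TRUE
  delta <- score_both(on)$wt - base$wt
  expect_true(all(abs(delta[!prof$alcohol_past_hour] - 1) < 1e-12))
})

test_that("score_analysis_set matches an independent per-record evaluator", {
  d <- random_labeled_records(1000, seed = 31)
  scored <- score_analysis_set(d)
  expect_equal(nrow(scored), 1000L)
  # literal re-evaluation of the printed formula, record by record
  for (i in sample.int(1000, 50)) {
    r <- d[i, ]
    expected_wt <- (r$urge - 3) * 0.2 + (r$stress - 3) * 0.2 +
      (r$availability - 3) * 0.7 + r$interacting_smoker + r$alcohol_past_hour -
      (r$motivation - 3) * 0.2
    expected_uw <- (r$urge >= 4) + (r$stress >= 4) + (r$motivation <= 2) +
      (r$availability >= 4) + r$interacting_smoker + r$alcohol_past_hour
    expect_equal(scored$weighted_risk_score[i], expected_wt)
    expect_equal(scored$n_risk_factors[i], as.integer(expected_uw))
  }
  # order preserved, empty input handled
  expect_equal(scored$urge, d$urge)
  expect_equal(nrow(score_analysis_set(d[0, ])), 0L)
  # records missing an item are dropped with a message
  d$stress[5] <- NA
  expect_message(out <- score_analysis_set(d), regexp = "1 record")
  expect_equal(nrow(out), 999L)
})

test_that("custom weights feed through and defaults reproduce the printed formula", {
  w <- risk_weights(w_urge = 0.5, w_alcohol = 2)
  expect_equal(weighted_score(5, 3, 3, 3, FALSE, TRUE, w), 0.5 * 2 + 2)
  expect_error(risk_weights(w_urge = Inf), class = "emalapse_validation_error")
  d <- risk_weights()
  expect_equal(
    unlist(d[c("offset", "w_urge", "w_stress", "w_motivation", "w_availability", "w_smoker_present", "w_alcohol")]),
    c(offset = 3, w_urge = 0.2, w_stress = 0.2, w_motivation = 0.2, w_availability = 0.7, w_smoker_present = 1, w_alcohol = 1)
  )
})

test_that("the count-score pmf matches brute-force enumeration over subsets", {
  prev <- c(0.593, 0.411, 0.173, 0.748, 0.336, 0.191)
  pmf <- risk_count_pmf(prev)
  # oracle: sum over all 2^6 indicator patterns
  oracle <- numeric(7)
  for (mask in 0:63) {
    bits <- as.integer(intToBits(mask))[1:6]
    oracle[sum(bits) + 1] <- oracle[sum(bits) + 1] +
      prod(ifelse(bits == 1, prev, 1 - prev))
  }
  expect_equal(unname(pmf), oracle, tolerance = 1e-12)
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
  expect_error(risk_count_pmf(c(0.5, 1.2)), class = "emalapse_validation_error")
})
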