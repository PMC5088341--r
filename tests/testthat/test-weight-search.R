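test_that("sensitivity and specificity agree with a direct tally", {
  d <- random_labeled_records(1000, seed = 5)
  w <- risk_weights()
  s <- weighted_score(
    d$urge, d$stress, d$motivation, d$availability,
    d$interacting_smoker, d$alcohol_past_hour, w
  )
  pos <- d$proximity_label == "WITHIN_4H"
  for (cutoff in c(-3, 0, 1, 2.2, 5)) {
    got <- evaluate_weights(d, w, cutoff)
    expect_equal(unname(got["sensitivity"]), sum(s > cutoff & pos) / sum(pos))
    expect_equal(unname(got["specificity"]), sum(s <= cutoff & !pos) / sum(!pos))
  }
  # degenerate cut-offs
  expect_equal(unname(evaluate_weights(d, w, min(s) - 1)), c(1, 0))
  expect_equal(unname(evaluate_weights(d, w, max(s) + 1)), c(0, 1))
  # single-class input is an error
  expect_error(
    evaluate_weights(d[pos, ], w, 1),
    class = "emalapse_validation_error"
  )
})

test_that("scaling weights and cut-off together leaves the operating point unchanged", {
  d <- random_labeled_records(600, seed = 9)
  w1 <- risk_weights()
  w2 <- risk_weights(
    w_urge = 0.4, w_stress = 0.4, w_motivation = 0.4,
    w_availability = 1.4, w_smoker_present = 2, w_alcohol = 2
  )
  expect_equal(evaluate_weights(d, w1, 1.0), evaluate_weights(d, w2, 2.0))
})

test_that("a singleton grid returns those weights with their own Youden value", {
  d <- random_labeled_records(800, seed = 13)
  cfg <- search_config(
    weight_grid_ordinal = c(0.2, 0.7), weight_grid_binary = 1
  )
  res <- grid_search(d, cfg)
  expect_equal(res$n_evaluated, 2^4 * 1) # exhaustiveness over the grid
  # independently recompute the winner's Youden at its cut-off
  op <- evaluate_weights(d, res$best_weights, res$best_cutoff)
  expect_equal(
    unname(op["sensitivity"] + op["specificity"] - 1),
    res$objective_value,
    tolerance = 1e-9
  )
  # the winner beats (or ties) every other vector on the grid
  for (i in seq_len(nrow(res$trace))) {
    expect_lte(res$trace$objective_value[i], res$objective_value + 1e-12)
  }

  # a true singleton containing only the study weights returns them
  one <- grid_search(d, search_config(
    weight_grid_ordinal = c(0.2, 0.7), weight_grid_binary = 1,
    cutoff_grid = c(0, 0.5, 1, 1.5)
  ))
  expect_true(one$best_cutoff %in% c(0, 0.5, 1, 1.5))
})

test_that("the search is deterministic and reports exhaustive evaluation", {
  d <- random_labeled_records(400, seed = 17)
  cfg <- search_config(
    weight_grid_ordinal = c(0, 0.5, 1), weight_grid_binary = c(0, 1)
  )
  a <- grid_search(d, cfg)
  b <- grid_search(d, cfg)
  expect_identical(a$best_weights, b$best_weights)
  expect_identical(a$objective_value, b$objective_value)
  expect_equal(a$n_evaluated, 3^4 * 2^2)
  # re-evaluation reproduces the reported objective
  op <- evaluate_weights(d, a$best_weights, a$best_cutoff)
  expect_equal(
    unname(op["sensitivity"] + op["specificity"] - 1),
    a$objective_value,
    tolerance = 1e-9
  )
})

test_that("the AUC objective ranks weight vectors by rank-based AUC", {
  d <- planted_signal_records(1500, seed = 23)
  cfg <- search_config(
    weight_grid_ordinal = c(0, 1), weight_grid_binary = 0, objective = "auc"
  )
  res <- grid_search(d, cfg)
  # cross-check the winner's objective against the exported rank AUC
  s <- weighted_score(
    d$urge, d$stress, d$motivation, d$availability,
    d$interacting_smoker, d$alcohol_past_hour, res$best_weights
  )
  expect_equal(
    res$objective_value, auc_rank(s, d$proximity_label == "WITHIN_4H"),
    tolerance = 1e-9
  )
  expect_equal(res$best_weights$w_availability, 1)
})

test_that("grid search recovers a planted availability-only signal", {
  cfg <- search_config(
    weight_grid_ordinal = c(0, 0.5, 1), weight_grid_binary = c(0, 0.5, 1)
  )
  hits <- 0L
  for (seed in 1:5) {
    d <- planted_signal_records(5000, seed = 400 + seed)
    res <- grid_search(d, cfg)
    if (recovered_availability(res$best_weights)) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("label-permuted data yields a near-zero objective", {
  cfg <- search_config(
    weight_grid_ordinal = c(0, 0.5, 1), weight_grid_binary = c(0, 0.5, 1)
  )
  for (seed in c(3, 44)) {
    d <- planted_signal_records(5000, seed = seed, permute_labels = TRUE)
    res <- grid_search(d, cfg)
    expect_lt(abs(res$objective_value), 0.1)
  }
})

test_that("degenerate search inputs are rejected", {
  d <- random_labeled_records(100, seed = 2)
  expect_error(
    grid_search(d[d$proximity_label == "ABSTAINER", ], search_config()),
    class = "emalapse_validation_error"
  )
  expect_error(search_config(weight_grid_ordinal = numeric(0)),
    class = "emalapse_validation_error"
  )
  expect_error(search_config(weight_grid_ordinal = c(-0.5, 1)),
    class = "emalapse_validation_error"
  )
})
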