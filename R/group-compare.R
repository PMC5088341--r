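#' Mixed-effects comparison of risk factors across proximity classes
#'
#' For each of the six dichotomized risk factors (logit link) and the
#' risk-factor count (identity link), fits a mixed-effects regression of
#' the outcome on proximity class with a participant-level random
#' intercept and a treatment-arm fixed effect, then reports every pairwise
#' class contrast with a Wald p-value. When a model fails to converge, or
#' a class is backed by fewer than two participants, the affected outcome
#' falls back to a seeded permutation test (never a silent fit): contrasts
#' between classes contributed by disjoint participants permute
#' participant group membership; the within-participant contrast
#' (imminent vs earlier pre-lapse EMAs of the same lapsers) permutes
#' labels within each participant's own records.
#'
#' @param scored Scored, labeled records from [score_analysis_set()]
#'   (needs `participant_id`, `arm`, `proximity_label`, the six indicator
#'   columns and `n_risk_factors`).
#' @param roster Participant roster (unused beyond validation; the
#'   grouping comes from the records).
#' @param outcomes Outcome columns to test.
#' @param n_perm Permutations for the fallback test.
#' @param seed Seed for the permutation fallback.
#' @param force_permutation Skip the mixed models entirely.
#' @return A tibble: `outcome`, `contrast`, `estimate` (model scale: log
#'   odds ratio for indicators, mean difference for the count),
#'   `p_value`, `method` (`"mixed"` or `"permutation"`).
#' @export
group_compare <- function(scored, roster = NULL,
                          outcomes = c(RISK_FACTORS, "n_risk_factors"),
                          n_perm = 2000L, seed = 1L,
                          force_permutation = FALSE) {
  d <- scored
  d$proximity_label <- droplevels(factor(d$proximity_label, levels = ANALYSIS_LEVELS))
  classes <- levels(d$proximity_label)
  if (length(classes) < 2L) {
    validation_abort("group comparison needs at least two proximity classes")
  }
  per_class_participants <- vapply(
    classes,
    function(k) length(unique(d$participant_id[d$proximity_label == k])),
    numeric(1)
  )
  thin_classes <- any(per_class_participants < 2)
  if (thin_classes && !force_permutation) {
    warn("a proximity class is backed by fewer than two participants; using the permutation test")
  }
  use_perm_all <- force_permutation || thin_classes

  pairs <- utils::combn(classes, 2, simplify = FALSE)
  use_arm <- length(unique(d$arm)) > 1L

  out <- lapply(seq_along(outcomes), function(oi) {
    outcome <- outcomes[oi]
    binary <- outcome != "n_risk_factors"
    res <- NULL
    if (!use_perm_all) {
      res <- tryCatch(
        mixed_contrasts(d, outcome, binary, use_arm, pairs),
        error = function(e) NULL
      )
      if (is.null(res)) {
        warn(sprintf(
          "mixed model for '%s' failed to converge; falling back to the permutation test",
          outcome
        ))
      }
    }
    if (is.null(res)) {
      res <- dplyr::bind_rows(lapply(seq_along(pairs), function(pi) {
        permutation_contrast(
          d, pairs[[pi]][1], pairs[[pi]][2], outcome,
          n_perm = n_perm, seed = seed + 1000L * oi + pi
        )
      }))
    }
    res$outcome <- outcome
    res
  })
  dplyr::bind_rows(out)[, c("outcome", "contrast", "estimate", "p_value", "method")]
}

mixed_contrasts <- function(d, outcome, binary, use_arm, pairs) {
  fml <- as.formula(paste(
    outcome, "~ proximity_label",
    if (use_arm) "+ arm" else "",
    "+ (1 | participant_id)"
  ))
  fit <- if (binary) {
    lme4::glmer(fml, data = d, family = binomial())
  } else {
    lme4::lmer(fml, data = d, REML = TRUE)
  }
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  if (any(grepl("failed to converge", msgs, ignore.case = TRUE))) {
    stop("non-convergence")
  }
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  coef_of <- function(class) {
    nm <- paste0("proximity_label", class)
    v <- setNames(numeric(length(beta)), names(beta))
    if (nm %in% names(beta)) v[nm] <- 1 # reference level contributes 0
    v
  }
  dplyr::bind_rows(lapply(pairs, function(pr) {
    cvec <- coef_of(pr[1]) - coef_of(pr[2])
    est <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    z <- est / se
    tibble::tibble(
      contrast = paste(pr[1], "vs", pr[2]),
      estimate = est,
      p_value = 2 * pnorm(-abs(z)),
      method = "mixed"
    )
  }))
}

# Permutation test of a class contrast in record-level means. The null is
# exchangeability of class labels: at the participant level when the two
# classes come from disjoint participants, within each participant's records
# when both classes come from the same lapsers.
permutation_contrast <- function(d, class_a, class_b, outcome, n_perm, seed) {
  sel <- d$proximity_label %in% c(class_a, class_b)
  dd <- d[sel, ]
  y <- as.numeric(dd[[outcome]])
  is_a <- dd$proximity_label == class_a
  stat <- function(a) mean(y[a]) - mean(y[!a])
  observed <- stat(is_a)

  within_participant <- length(intersect(
    unique(dd$participant_id[is_a]), unique(dd$participant_id[!is_a])
  )) > 0

  set.seed(seed)
  perm_stats <- if (within_participant) {
    split_idx <- split(seq_len(nrow(dd)), dd$participant_id)
    vapply(seq_len(n_perm), function(b) {
      a <- logical(nrow(dd))
      for (idx in split_idx) {
        a[idx] <- sample(is_a[idx])
      }
      stat(a)
    }, numeric(1))
  } else {
    pid <- dd$participant_id
    groups <- !duplicated(pid)
    pid_a <- unique(pid[is_a])
    all_pid <- unique(pid)
    n_a <- length(pid_a)
    vapply(seq_len(n_perm), function(b) {
      new_a <- sample(all_pid, n_a)
      stat(pid %in% new_a)
    }, numeric(1))
  }
  p <- (1 + sum(abs(perm_stats) >= abs(observed) - 1e-12)) / (1 + n_perm)
  tibble::tibble(
    contrast = paste(class_a, "vs", class_b),
    estimate = observed,
    p_value = p,
    method = "permutation"
  )
}
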