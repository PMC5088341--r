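---
title: "Momentary lapse-risk estimation: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Momentary lapse-risk estimation: models, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emalapse)
```

## The estimation problem

During the first week of a quit attempt, participants answer brief mobile
surveys several times a day: four ordinal items on a 1–5 scale (urge to
smoke, stress, commitment to being smoke free, cigarette availability) and
two yes/no items (interacting with someone smoking, alcohol within the
last hour). The question the package answers is whether those six
momentary reports, combined into a single score, discriminate the moments
when a first lapse is imminent — defined as occurring within the next
4 hours — from all other pre-lapse and abstainer moments.

Two estimators are implemented:

* the **unweighted count score**: each item is dichotomized (urge and
  stress endorsed at response 4–5; low motivation at 1–2; availability at
  4–5, i.e. "fairly easily" or "easily available"; the binaries as
  answered) and the positives are counted, giving a 0–6 score;
* the **weighted linear score**: each ordinal item is centered at the
  neutral response 3 and multiplied by a coefficient (0.2 for urge, stress
  and motivation — motivation entering negatively because commitment is
  protective — and 0.7 for availability), with the two binaries entering
  at full weight:
  $$s = 0.2(u-3) + 0.2(x-3) + 0.7(a-3) + \mathbb{1}_{\text{smoker}} + \mathbb{1}_{\text{alcohol}} - 0.2(m-3).$$

Exhaustive enumeration of all $5^4 \times 2^2 = 2{,}500$ response profiles
gives an achievable range of $[-2.6, 4.6]$ for the weighted score. The
source analysis states the upper end of this range as 4.2, which is
inconsistent with its own printed formula (the all-risk profile
$u=x=5, m=1, a=5$, both binaries yes, evaluates to
$0.4+0.4+1.4+1+1+0.4 = 4.6$); the package follows the formula and reports
the discrepancy rather than silently altering either number.

Classification uses the strict convention *score > cutoff flags the EMA*.
A published operating point phrased as "3 or more risk factors" is
reproduced by the strict threshold 2.5 on the integer count score;
`eval_report()` applies this `c − 0.5` mapping automatically, and the CLI
exposes a `--ge-cutoffs` flag with the same meaning.

## What the synthetic cohort emulates

The original EMA dataset is not deposited, so `generate_cohort()`
produces seeded cohorts with the study's design, and every downstream
stage is tested against them. The generator emulates:

* **Sampling design** — 52 lapsers and 40 abstainers; 7 post-quit days; a
  daily diary 30 minutes after waking plus four random prompts over a
  16-hour waking window (starting 08:00), random prompts at least 90
  minutes apart; urge-triggered self-initiated EMAs as a Poisson process;
  a lapse-report EMA placed within 30 minutes before the lapse with
  probability 0.9. Prompted EMAs are completed independently with
  probability 0.9. With the self-initiation rate of 1.6/day these defaults
  give an expected ≈ 43 completed EMAs per participant, matching the
  study's observed mean of 43.5; the rate and compliance split between
  prompted and self-initiated volume is our choice, as only the total is
  published.
* **Lapse timing** — uniform over the waking portions of days 1–7,
  excluding the first four waking hours so a pre-lapse window always
  exists; no published lapse-time distribution exists, and uniformity is
  the minimal assumption.
* **Proximity-conditional item distributions** — the published risk-factor
  prevalences are conditional on proximity class (within 4 h of the first
  lapse / more than 4 h before it / abstainer), so items are drawn
  conditional on the class each EMA will eventually occupy. A
  time-homogeneous generator could not reproduce those class-conditional
  margins. Post-lapse EMAs, which never enter any analysis, reuse the
  over-4-hour vector; the choice is unobservable downstream.
* **Ordinal reconstruction** — only dichotomized prevalences are
  published, so `map_prevalence_to_ordinal()` places the target mass $p$
  on the indicator-positive categories with a fixed split (60/40 across
  4/5 for agree-keyed items, mirrored for motivation) and the remaining
  mass 20/40/40 across the others. The split is arbitrary but fixed; only
  the dichotomized mass matters to any downstream quantity.
* **Optional dependence** — a single shared Gaussian copula factor with
  loading $\sqrt{\rho}$ per item induces positive inter-item correlation
  while preserving the marginals (categories are ordered least- to
  most-risky per item, so large factor values push all six indicators
  toward risk together). The default is $\rho = 0$ (independence).

**What independence does and does not reproduce.** Quantities driven by
the class-conditional margins reproduce the published values: the mean
count of risk factors per class (analytic expectations 2.452, 1.852,
1.278 against published 2.43, 1.83, 1.27) and the share of imminent-lapse
EMAs with ≥ 3 factors (Poisson-binomial tail 47.3% against published
47.2%). Correlation-sensitive quantities do not: the published abstainer
≥ 3-factor rate of 11.90% exceeds the independence prediction of 8.9%,
which is direct evidence of positive inter-item correlation in the real
data. That gap is why the copula knob exists; correlation-dependent
results under the generator are sensitivity analyses, not calibrated
truth. For the same reason the real-data AUCs (0.72 unweighted, 0.76
weighted) and the weighted estimator's advantage are **not** expected from
the independence generator, and passing tests say nothing about them.
Within-person autocorrelation and informative missingness are not
modelled at all.

## Windowing conventions

`label_proximity()` gives each EMA exactly one of five labels; only
`WITHIN_4H`, `PRE_LAPSE_OVER_4H` and `ABSTAINER` enter analyses. Three
boundary conventions were genuinely open and are fixed as follows:

* a gap of exactly the window length (lapse at 18:00, EMA at 14:00) is
  *within* the window — the interval is closed;
* an EMA time-stamped at the lapse instant is post-lapse: the lapse-report
  EMA itself is not a predictor observation;
* windows are measured in calendar time, not waking time.

Records before the quit time are dropped with a warning (the pre-quit week
is out of scope), and inconsistent reporters are excluded wholesale,
overriding every other label. Timestamps are ISO-8601 at minute
resolution in a single study timezone; booleans serialize as
`yes`/`no`.

## The weight search

The published procedure is an iterative examination of candidate weights
(steps of 0.1) maximizing "sensitivity and specificity"; the exact grids
and objective are not published. `grid_search()` therefore makes both
configurable, with defaults documented as assumptions:

* ordinal-coefficient grid $\{0.0, 0.1, \ldots, 1.0\}$, binary grid
  $\{0, 0.5, 1\}$ — $11^4 \times 3^2 = 131{,}769$ vectors, evaluated
  exhaustively;
* objective: Youden's $J = \text{sens} + \text{spec} - 1$ maximized over
  all cut-offs (every midpoint between adjacent observed scores), with
  rank-based AUC as the alternative;
* motivation's coefficient is constrained non-negative and always enters
  negatively, matching the estimator's sign convention;
* ties are broken by smallest $L_1$ norm, then lexicographic order of the
  coefficient tuple — fully deterministic;
* no train/test split by default, replicating the original
  fit-and-evaluate-on-the-same-data procedure and its acknowledged
  overfitting risk.

Records are internally collapsed to unique response profiles (at most
2,500) with per-class counts, so the cost per weight vector is independent
of the record count; the full default grid evaluates in well under a
minute on a study-sized analysis set.

One identifiability point matters for interpreting search results: $J$ is
invariant to rescaling all weights and the cut-off by a common positive
factor, so coefficients are recovered only up to scale, and a noise item
sitting exactly on a flagging boundary can tie the leading coefficient.
The planted-signal recovery test in the suite accordingly checks that the
availability coefficient strictly dominates the other ordinal items and
is matched by no other coefficient, not that a specific vector is
returned.

## Evaluation machinery

* **AUC** is the rank (Mann–Whitney) statistic with ties counted ½,
  identical by construction to the trapezoidal area under the empirical
  ROC curve; the test suite verifies both identities against an $O(n^2)$
  pairwise oracle. The 95% CI uses the asymptotic variance of the rank
  statistic (DeLong), not a binormal fit — the source states CIs without
  a method, and the rank-based variance makes no distributional
  assumption.
* **Correlated-ROC comparison** of the weighted vs unweighted scores uses
  the DeLong structural-components test (the source does not name its
  test; output is labelled accordingly), with a seeded paired bootstrap
  (2,000 resamples) as an alternative; the two agree to within 0.02 on
  moderate samples. Identical score vectors, or vectors differing by a
  monotone shift, return $p = 1$ by rank invariance.
* **Clustering** — the published AUC analysis treats EMAs as independent
  despite repeated measures per participant; the default replicates that
  choice. The record-resampling bootstrap shares the limitation by
  design.
* **Group comparisons** fit mixed-effects regressions (logit link for the
  six indicators, identity link for the count) with a participant random
  intercept and a treatment-arm fixed effect, reporting pairwise class
  contrasts as Wald tests on linear combinations of the fixed effects.
  Under the independence generator the random-intercept variance is
  genuinely zero, so singular fits are routine and harmless. When a model
  fails to converge or a class is backed by fewer than two participants,
  the outcome falls back to a seeded permutation test (2,000 permutations)
  rather than a silent fit. Exchangeability is imposed at the participant
  level for contrasts between classes contributed by disjoint
  participants; the imminent-vs-earlier contrast compares records of the
  same lapsers, where no participant-level relabelling preserves the
  design, so labels are permuted within each participant's own records.

## Problem sizes and numerical choices

The test suite simulates at sizes chosen to make its statistical
assertions sharp at three standard errors: 100,000 item draws for
prevalence-recovery and tail checks (binomial SE ≈ 0.16 points on a
percentage), 5,000 records × 20 seeds for planted-weight recovery, 200
null replicates for type-I calibration of the group contrasts, and
$n \le 1{,}000$ for the quadratic AUC oracle. Score ties in the search are
collapsed at $10^{-12}$, well below the $0.05$ granularity of grid-induced
score differences; the search result's objective is reproducible by
re-evaluation to within $10^{-9}$.

## Known limitations

* The generator draws items independently across EMAs: no within-person
  autocorrelation, no informative missingness, no pre-quit week, and no
  treatment-arm effect on lapse timing (arm is assigned but inert).
* Real-data headline numbers that depend on inter-item correlation —
  the AUC pair, the weighted estimator's advantage, the abstainer
  ≥ 3-factor rate — are out of reach of the independence defaults by
  construction, and deliberately so: they are not asserted anywhere.
* Only the first lapse is modelled; multi-lapse trajectories are out of
  scope.
* The weight search reproduces a grid procedure, not a regularized or
  gradient-based fit; with no held-out data its objective values are
  optimistic in-sample quantities.
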