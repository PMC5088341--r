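# emalapse

Real-time smoking-lapse risk estimation from ecological momentary
assessments (EMAs).

## The problem

Smokers attempting to quit are most likely to be helped by an intervention
delivered *just before* a lapse, not days later at a clinic visit. Mobile
phones make it possible to collect brief in-the-moment surveys (EMAs) many
times a day during the first post-quit week and to ask: **do the risk
factors reported right now signal that a first lapse is imminent (within
the next 4 hours)?**

`emalapse` implements that analysis end to end, for biostatisticians and
mHealth researchers building just-in-time adaptive interventions:

1. **Domain I/O** — validated CSV reading/writing of EMA records (four
   5-point ordinal items: urge to smoke, stress, cessation motivation,
   cigarette availability; two binary items: interacting with a smoker,
   alcohol in the past hour) and a participant roster (arm, quit time,
   first-lapse time).
2. **Synthetic cohorts** — a seeded generator emulating the motivating
   study's design (92 participants: 52 lapsers, 40 abstainers; one
   wake-anchored daily diary plus four random prompts per day over a
   16-hour waking window for 7 post-quit days, plus self-initiated EMAs)
   with risk-factor prevalences conditional on lapse proximity. The study's
   raw data are not deposited, so the generator is the test bed for every
   downstream stage.
3. **Lapse windowing** — each EMA is labelled `WITHIN_4H`,
   `PRE_LAPSE_OVER_4H`, or `ABSTAINER`; post-lapse EMAs and inconsistent
   reporters are excluded.
4. **Risk scoring** — the six items are dichotomized (agree/strongly agree
   endorses urge and stress; disagree/strongly disagree endorses low
   motivation; fairly easily/easily available endorses availability) into
   an unweighted count score in 0–6, and a weighted linear score

   ```
   risk = 0.2·(urge − 3) + 0.2·(stress − 3) + 0.7·(availability − 3)
        + 1·[smoker present] + 1·[alcohol past hour] − 0.2·(motivation − 3)
   ```

   whose achievable range over all 2,500 response profiles is −2.6 to 4.6.
5. **Weight search** — exhaustive grid search over per-item coefficients
   maximizing Youden's J (sensitivity + specificity − 1) over all
   cut-offs, with deterministic tie-breaking.
6. **Evaluation** — prevalence tables by proximity class, operating points,
   participant-level detection, rank-based (Mann–Whitney) AUC with DeLong
   confidence intervals, correlated-ROC comparison of the weighted vs
   unweighted estimators, and mixed-effects group comparisons with a
   seeded permutation fallback.

## Worked example

```r
library(emalapse)

cohort  <- generate_cohort(sim_config(master_seed = 2026))
cohort
#> <ema_cohort> 92 participants (52 lapsers, 40 abstainers), 3954 EMA records

labeled <- build_analysis_set(cohort)
#> analysis set: 122 within-window, 1134 pre-lapse beyond window, 1693 abstainer;
#> excluded 1005 post-lapse, 0 inconsistent

scored  <- score_analysis_set(labeled)
report  <- eval_report(scored, cohort$participants, group_tests = FALSE)
report
#> <lapse_eval_report> 2949 records (122 imminent-lapse)
#>   unweighted: sens 38.5% / spec 84.3% (cutoff 2.5); AUC 0.70 (0.66-0.74)
#>   weighted:   sens 53.3% / spec 72.5% (cutoff 1.0); AUC 0.67 (0.62-0.72)
#>   AUC comparison (weighted vs unweighted, delong): p = 0.09212
#>   participant detection: unweighted 69%, weighted 83%
```

Reading the output: of the 122 EMAs completed within 4 hours of a first
lapse, 38.5% endorsed three or more risk factors (the unweighted cut-off),
while 84.3% of all other retained EMAs stayed below it; 83% of lapsers had
at least one imminent-lapse EMA whose weighted score exceeded 1.0. These
are *synthetic-cohort* numbers: the generator draws the six items
independently at the published class-conditional prevalences, so
quantities driven by those margins (class mean counts, the ≥3-factor rate
among imminent EMAs) reproduce the published values, while
correlation-sensitive quantities (AUCs, the weighted estimator's edge) are
not expected to match the real data.

The exact Poisson-binomial tail of the count score under independence:

```r
pmf <- risk_count_pmf(c(0.593, 0.411, 0.173, 0.748, 0.336, 0.191))
round(100 * sum(pmf[as.character(3:6)]), 1)
#> [1] 47.3
```

A one-command pipeline (simulate → window → score → optimize → evaluate)
with a reproducibility manifest:

```r
manifest <- run_pipeline(list(simulate = list(n_lapsers = 52, n_abstainers = 40)),
                         out_dir = "run1", seed = 1)
```

A thin command-line wrapper with the same subcommands is installed at
`inst/exec/emalapse`.

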