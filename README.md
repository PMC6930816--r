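# incns

Severity scoring and prognostic validation for neurocritically ill patients.

Patients in a neurological ICU are poorly served by the general-ICU
prognostic scores (APACHE II, SAPS II): those models carry no assessment of
neurological deficit, which is precisely what drives functional outcome in
this population. The INCNS score addresses that gap: a 19-item, 0–44 point
bedside score organized in five categories — **I**nflammation (WBC,
temperature), **N**utrition (albumin), **C**onsciousness (arousal,
awareness), **N**eurologic function (pupillary and corneal reflexes, verbal,
motor, swallowing, respiration) and **S**ystemic condition (age, vitals,
labs) — each item weighted 0–3, designed to predict the 3-month functional
outcome (modified Rankin Scale dichotomized at mRS ≥ 3 = unfavorable).

This package provides, as production R code:

* the full INCNS scoresheet (`score_incns()`, `score_item()`), with
  deterministic decimal binning, a strict or flagged-imputation missing-data
  policy, and a bundled declarative JSON transcription of the bin tables;
* the comparator scores from their original definitions: `score_gcs()`,
  `score_four()`, `score_apache2()` (0–71), `score_saps2()` (0–163);
* worst-value windowing of longitudinal observations over the first 24 h or
  72 h (`worst_snapshot()`, `score_cohort()`);
* the validation battery (`roc()`, `auc_ci_and_compare()` — DeLong,
  `youden_cutoff()`, `mcnemar_paired()`, `compare_predictive_values()`,
  `fit_outcome_probability()`, `validation_report()`);
* a seeded synthetic-cohort generator with a latent-severity ground truth
  (`cohort_spec()`, `simulate_cohort()`, `calibrate_latent_effect()`);
* a CSV/JSON command-line interface (`incns_main()`; launcher at
  `inst/cli/incns.R`).

## Statistical core

For scores $S$ and binary outcomes $D$ on the same patients, discrimination
is the Mann–Whitney AUC
$\widehat{A} = \frac{1}{n_1 n_0}\sum_{i:D_i=1}\sum_{j:D_j=0}
\left[\mathbb{1}(S_i > S_j) + \tfrac12\mathbb{1}(S_i = S_j)\right]$,
with DeLong placement-value variance, logit-scale 95% CIs, and the paired
z-test on $\widehat{A}_1 - \widehat{A}_2$ for correlated AUCs. The operating
cutoff $c^\*$ maximizes the Youden index $J = \text{sens} + \text{spec} - 1$
(rule: score ≥ c predicts unfavorable). Paired classifiers are compared with
McNemar's test on discordant counts (exact binomial below 25 discordant
pairs) for sensitivity/specificity/CC, and with a Wald test on the log
relative predictive value for PPV/NPV. Families of score-vs-score
comparisons are judged at α = 0.0167, single tests at α = 0.05.

## Worked example

Score one patient snapshot:

```r
library(incns)
snap <- patient_snapshot(
  age = 70, wbc = 12, temperature_ax = 39, albumin = 30,
  arousal = "to_pain", awareness = "nonreflex_movements",
  pupillary_reflex = "unilateral_slow_absent",
  corneal_reflex = "bilateral_sensitive",
  motor_mode = "pain_response", motor_pain = "flexes_extends",
  swallow = "wst_III_IV_or_unable",
  intubated = TRUE, vent_interaction = "above_rate",
  verbal = "incomprehensible_none",
  heart_rate = 110, sbp = 150, glucose = 12, sodium = 155,
  potassium = 3, creatinine = 180, bilirubin = 40)
score_incns(snap)
#> INCNS score: 26 / 44
#>   inflammation        2
#>   nutrition           1
#>   consciousness       4
#>   neurologic_function 9
#>   systemic_condition  10
```

Simulate a cohort, abstract worst values over 72 h, and run the validation
battery against APACHE II:

```r
co   <- simulate_cohort(cohort_spec(n_patients = 400, seed = 7))
inc  <- score_cohort(co$observations, 72, "incns")
ap   <- score_cohort(co$observations, 72, "apache2", assume_normal = TRUE)
scores <- data.frame(patient_id = inc$patient_id,
                     incns = inc$score, apache2 = ap$score)
validation_report(scores, co$outcomes,
                  compare = list("incns:apache2"), window = 72)
#> Validation report (72 h window)
#>   cohort: n=400, unfavorable 60.5%, died 25.0%
#>   incns     AUC 0.828 (0.783-0.865) cutoff>=29 sens 0.785 spec 0.747 CC 0.770
#>   apache2   AUC 0.833 (0.790-0.869) cutoff>=23 sens 0.826 spec 0.709 CC 0.780
#>   incns:apache2: dAUC -0.006 (p=0.5539)
```

The cohort summary line recomputes the outcome proportions from the
simulated mRS grades; the AUC line gives the DeLong logit-scale 95% CI and
the confusion metrics at the Youden cutoff; the comparison line is the
paired DeLong test (judged at the multiple-comparison α = 0.0167). In this
synthetic world INCNS and APACHE II draw on the same latent severity, so
their AUCs are similar by construction — the real-data superiority of the
neuro-specific score is a property of real patients, not something the
simulator asserts.

Map scores to outcome probabilities:

```r
lab <- co$outcomes$unfavorable[match(inc$patient_id, co$outcomes$patient_id)]
fit <- fit_outcome_probability(inc$score, lab)
#> intercept -3.19, slope 0.131; P(unfavorable | score = 9) = 0.12
```

Note: GCS and FOUR totals decrease with severity; feed their derangement
transforms (`15 - gcs`, `16 - four`) to the ROC machinery, whose convention
is "higher score predicts unfavorable".

## Command line

```sh
Rscript inst/cli/incns.R simulate --n 941 --seed 1 --out cohort/
Rscript inst/cli/incns.R score    --input cohort/observations.csv \
    --window 72 --score incns,apache2,saps2 --out cohort/scores.csv
Rscript inst/cli/incns.R validate --scores cohort/scores.csv \
    --outcomes cohort/outcomes.csv \
    --compare incns:apache2,incns:saps2 --out cohort/report.json
```

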