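---
title: "Methods: the INCNS score, its comparators, and the validation battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the INCNS score, its comparators, and the validation battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(incns)
```

## The scoring model

The INCNS score summarizes the acute condition of a neurocritically ill
patient as an integer between 0 and 44. It has 19 items in five categories —
inflammation (WBC, axillary temperature), nutrition (serum albumin),
consciousness (arousal by eye-opening, awareness by behavioral tests),
neurologic function (pupillary light reflex, corneal reflex, verbal response,
motor response, 30 mL water-swallow test, respiration), and systemic
condition (age, heart rate, systolic blood pressure, random glucose, sodium,
potassium, creatinine, total bilirubin). Each item contributes 0–3 points
(0 = normal); category maxima are 4 / 2 / 6 / 15 / 17.

Item conventions that differ from the familiar consciousness scales:

* **Motor**: either a muscle-strength test or a pain-response test is
  performed, never both. On the strength path the *worst* limb's MRC grade is
  used (grade ≥ 4 → 0, 2–3 → 1, ≤ 1 in one limb → 2, ≤ 1 bilaterally → 3);
  on the pain path obeying/localizing/flexing/none map to 0–3.
* **Verbal**: intubated patients are always scored "incomprehensible
  speech/none" (2 points). The scorer enforces this, with a warning when a
  conflicting verbal value was recorded.
* **Respiration** has four degrees: not intubated with a rate of 12–24 (0);
  not intubated, rate ≤ 11 or ≥ 25 (1); breathing above the ventilator rate
  (2); breathing at the ventilator rate or apnea (3).
* **Brainstem reflexes** (pupillary, corneal) take points {0, 2, 3} only —
  slow or absent responses are deliberately up-weighted.
* **Swallowing**: water-swallow test III–IV *or unable to assess* scores 1.

### Numeric binning

The printed scoresheet uses closed decimal bins with gaps between them
(e.g. WBC 4–10 vs 10.1–25.0). To make binning total and deterministic, every
input is first rounded to the row's printed precision (one decimal for WBC,
temperature, albumin, glucose, potassium, bilirubin; integers for sodium,
creatinine, heart rate, SBP, respiratory rate, age; R's default IEC 60559
half-to-even rounding), after which the printed bins tile the whole axis.
Lookups are done in scaled-integer arithmetic, so floating-point
representation can never move a value across a bin edge. The bin tables also
ship as a versioned JSON resource (`load_bin_table("incns")`) and the test
suite diffs the code tables against that declarative transcription;
transcription error, not logic, is the dominant risk for score
implementations.

### Missing data

The source description is silent on missing values. The default here is a
hard error naming the missing raw fields. An explicit `assume_normal = TRUE`
(CLI `--assume-normal`) scores missing items 0 and flags them in the result
(`imputed`, `n_imputed`), because silent imputation biases severity downward
and flagged imputation keeps the audit trail.

## Comparator scores

GCS (3–15) and FOUR (0–16) are validated component sums. APACHE II (0–71)
and SAPS II (0–163) are transcribed from their original publications:
12 worst-value physiology items plus age and chronic-health points for
APACHE II (creatinine doubled in acute renal failure, GCS item scored
15 − GCS, A-a gradient used when FiO₂ ≥ 0.5 and PaO₂ otherwise, bicarbonate
replacing pH when no blood gas exists); 17 irregularly weighted variables
for SAPS II (PaO₂/FiO₂ scored only in ventilated patients, admission type
and chronic disease included — the comparators stay faithful to their own
definitions even where the INCNS design dropped comorbidities). Both tables
are also diffed against independent JSON transcriptions, and both published
maxima (71 and 163) are reproduced by extremal-input tests.

The comparator input type extends the snapshot with MAP, core temperature
(axillary is used as a fallback), oxygenation, acid–base, hematocrit, urine
output, urea, chronic-health flags and the GCS/FOUR components. Note the
classification convention of the validation battery is "higher score predicts
unfavorable outcome"; GCS and FOUR totals run the other way, so use their
derangement transforms (15 − GCS, 16 − FOUR) when feeding them to the ROC
machinery.

## Worst-value windowing

A patient's time-stamped observations are reduced to the most deranged
reading during the first 24 h and 72 h. "Most deranged" is interpreted
*per item*: for each scoresheet item independently, the in-window reading
that maximizes that item's points is selected (ties go to the earliest
qualifying reading, for reproducibility). The assembled snapshot may
therefore mix time points — this mirrors how worst-value severity scores are
abstracted in practice, but it is an interpretation: the source does not say
whether its abstraction was per-variable or per-time-point. Composite items
(motor, respiration, oxygenation) travel as a unit from a single reading, so
no impossible field combinations can be assembled. The window boundary is
closed: a reading at exactly admission + 24 h counts for the 24 h window.

## The validation battery

* **ROC/AUC**: empirical ROC over all distinct thresholds under the rule
  "score ≥ cutoff predicts unfavorable"; AUC is the mid-rank Mann–Whitney
  statistic, identical to the trapezoidal area of the tie-merged curve and
  to the pairwise win-fraction oracle the tests enumerate.
* **Confidence intervals and paired comparison**: DeLong placement-value
  variance and covariance. The paired AUC difference is tested with the
  standard two-sided z-test. The 95% CI is a normal approximation *on the
  logit scale* (delta method on the DeLong SE): it respects [0, 1] and, in
  coverage simulations at n = 200 and AUC 0.8, achieves ≈ 95.0% coverage
  versus ≈ 94.1% for the untransformed interval. The CI method used in the
  original validation is unstated; this choice is recorded as an
  interpretation.
* **Youden cutoff**: exhaustive over observed thresholds, maximizing
  sensitivity + specificity − 1 in exact integer arithmetic
  (tp·n₀ − fp·n₁), smallest cutoff on ties; full confusion metrics
  (sensitivity, specificity, PPV, NPV, CC) are reported at the selected
  cutoff.
* **McNemar tests** compare sensitivity (within truly unfavorable
  patients), specificity (within truly favorable patients) and CC (all
  patients) of two paired classifiers. The statistic is the
  continuity-corrected χ² (|b−c|−1)²/(b+c); the p-value uses the χ² when
  b + c ≥ 25 and the exact two-sided binomial otherwise; b + c = 0 returns
  p = 1 by convention.
* **PPV/NPV comparison**: the named "modification of Wald tests" is not
  spelled out in the source; implemented as a Wald test on the log relative
  predictive value with a multinomial delta-method variance over the eight
  paired cells (prediction A × prediction B × outcome), with a 0.5
  continuity correction when a required cell group is empty. Cross-checked
  against a paired bootstrap and calibrated to ≈ 5% type-I error in null
  simulations. Flagged as an interpretation.
* **Probability map**: a univariate logistic regression of the binary
  outcome on the integer score, evaluated at scores 0–44. Complete or
  quasi-complete separation triggers a fall back to Firth's bias-reduced
  fit (Jeffreys-prior score adjustment), and the result is flagged.
* **Significance levels**: 0.05 for single comparisons, 0.0167 for the
  family of score-vs-score performance comparisons.

## The synthetic cohort

No patient data are distributed, so validation runs on synthetic cohorts
with known ground truth. Per patient a latent severity *z* ~ N(0, 1) drives
everything:

* **Outcome first**: the 3-month mRS comes from an ordinal-logistic link on
  *z* (slope 2.0) whose cutpoints are calibrated by numerical integration so
  the marginal unfavorable fraction is 0.592 and the death fraction 0.247 —
  the published cohort's proportions. Observed variables are generated from
  *z*, never from the outcome, so there is no label leakage and
  discrimination is imperfect by construction.
* **Variables by item level**: each scoresheet item follows a
  proportional-odds model on its own point levels,
  P(points ≥ j | z) = logit⁻¹(θⱼ + λ·z), with baseline marginals 0.35 /
  0.12 / 0.04 for levels ≥ 1 / ≥ 2 / ≥ 3 and a shared link strength λ
  (`latent_effect`). The sampled level is converted back to a raw value
  drawn uniformly inside a bin of that level (the high side is taken with
  probability 0.7 where a level has bins on both sides of normal). Every
  generated reading is guaranteed scorable.
* **Longitudinal structure**: a complete panel at admission (t = 0), then
  2–4 readings per window; each reading perturbs the latent signal with
  N(0, 0.5²) noise. Readings after 24 h multiply *z* by `late_gain = 1.3`,
  emulating progressive worsening beyond the first day — this is what makes
  the 72 h worst-value score discriminate at least as well as the 24 h one,
  which the acceptance suite verifies as a property across 200 seeds rather
  than as a numeric claim.
* **Link strength**: `calibrate_latent_effect()` bisects λ against a target
  AUC. At n = 941 the achievable 72 h AUC plateaus near 0.825 ± 0.005 (the
  per-reading noise bounds discrimination); the default λ = 1.30 sits at
  that plateau, within ±0.03 of the 0.828 target.
* **Comparator plumbing**: GCS/FOUR components are derived consistently
  from the sampled consciousness and motor levels; comparator-only
  continuous variables (MAP, blood gas, hematocrit, urine output, urea) are
  monotone-in-*z* Gaussian or log-normal draws. Patient-level flags
  (admission type, chronic disease, organ insufficiency) use fixed realistic
  frequencies.

What the generator does **not** emulate: etiology mixture, correlated
multi-organ failure patterns, informative missingness, repeated-measure
autocorrelation beyond the shared latent, or any real marginal distribution
of labs. A green pipeline test therefore establishes computational
correctness and qualitative structure (ordering of windows, effect of
ablation, calibration of the test statistics) — not clinical validity, and
not the published cohort-specific AUCs, whose dataset is not deposited.

## Numerical and edge-case choices

* Degenerate inputs are rejected early: single-class label vectors,
  constant scores (undefined DeLong variance), classifiers predicting no
  positives (undefined PPV), prevalences of 0 or 1 in the simulator.
* Identical paired inputs short-circuit to p = 1 (AUC, PPV/NPV, McNemar),
  so self-comparisons are exactly null.
* All randomness flows through explicit seeds; `simulate_cohort()` restores
  the caller's RNG state.
* The worst-value selector breaks point ties by the earliest reading, making
  cohort scoring invariant to record order.

## Known limitations

* APACHE II expects a core temperature and a recorded respiratory rate even
  under ventilation; the observation schema records axillary temperature
  (used as a fallback) and no spontaneous rate for intubated patients, so
  APACHE II on simulated cohorts is typically scored with the flagged
  assume-normal policy for those items.
* The per-variable worst-value interpretation, the logit-scale CI, and the
  relative-predictive-value Wald construction are documented
  interpretations of underspecified methods, each validated against an
  independent oracle (brute force, bootstrap, or simulation) in the test
  suite.
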