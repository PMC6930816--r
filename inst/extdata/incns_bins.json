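{
  "version": "1.0",
  "score": "incns",
  "max_total": 44,
  "category_maxima": {
    "inflammation": 4,
    "nutrition": 2,
    "consciousness": 6,
    "neurologic_function": 15,
    "systemic_condition": 17
  },
  "numeric_items": {
    "wbc": {"digits": 1, "bins": [
      {"lo": null, "hi": 2.8, "points": 2},
      {"lo": 2.9, "hi": 3.9, "points": 1},
      {"lo": 4, "hi": 10, "points": 0},
      {"lo": 10.1, "hi": 25.0, "points": 1},
      {"lo": 25.1, "hi": null, "points": 2}]},
    "temperature_ax": {"digits": 1, "bins": [
      {"lo": null, "hi": 35.9, "points": 1},
      {"lo": 36, "hi": 38.4, "points": 0},
      {"lo": 38.5, "hi": 40, "points": 1},
      {"lo": 40.1, "hi": null, "points": 2}]},
    "albumin": {"digits": 1, "bins": [
      {"lo": null, "hi": 24.9, "points": 2},
      {"lo": 25, "hi": 34.9, "points": 1},
      {"lo": 35, "hi": null, "points": 0}]},
    "age": {"digits": 0, "bins": [
      {"lo": null, "hi": 44, "points": 0},
      {"lo": 45, "hi": 64, "points": 1},
      {"lo": 65, "hi": 74, "points": 2},
      {"lo": 75, "hi": null, "points": 3}]},
    "heart_rate": {"digits": 0, "bins": [
      {"lo": null, "hi": 39, "points": 2},
      {"lo": 40, "hi": 59, "points": 1},
      {"lo": 60, "hi": 100, "points": 0},
      {"lo": 101, "hi": 149, "points": 1},
      {"lo": 150, "hi": null, "points": 2}]},
    "sbp": {"digits": 0, "bins": [
      {"lo": null, "hi": 69, "points": 2},
      {"lo": 70, "hi": 89, "points": 1},
      {"lo": 90, "hi": 140, "points": 0},
      {"lo": 141, "hi": 199, "points": 1},
      {"lo": 200, "hi": null, "points": 2}]},
    "glucose": {"digits": 1, "bins": [
      {"lo": null, "hi": 2.1, "points": 2},
      {"lo": 2.2, "hi": 3.8, "points": 1},
      {"lo": 3.9, "hi": 11.1, "points": 0},
      {"lo": 11.2, "hi": 19.3, "points": 1},
      {"lo": 19.4, "hi": null, "points": 2}]},
    "sodium": {"digits": 0, "bins": [
      {"lo": null, "hi": 119, "points": 2},
      {"lo": 120, "hi": 129, "points": 1},
      {"lo": 130, "hi": 150, "points": 0},
      {"lo": 151, "hi": 159, "points": 1},
      {"lo": 160, "hi": null, "points": 2}]},
    "potassium": {"digits": 1, "bins": [
      {"lo": null, "hi": 2.4, "points": 2},
      {"lo": 2.5, "hi": 3.4, "points": 1},
      {"lo": 3.5, "hi": 5.5, "points": 0},
      {"lo": 5.6, "hi": 6.9, "points": 1},
      {"lo": 7.0, "hi": null, "points": 2}]},
    "creatinine": {"digits": 0, "bins": [
      {"lo": null, "hi": 43, "points": 1},
      {"lo": 44, "hi": 132, "points": 0},
      {"lo": 133, "hi": 171, "points": 1},
      {"lo": 172, "hi": null, "points": 2}]},
    "bilirubin": {"digits": 1, "bins": [
      {"lo": null, "hi": 34.1, "points": 0},
      {"lo": 34.2, "hi": 102.5, "points": 1},
      {"lo": 102.6, "hi": null, "points": 2}]}
  },
  "enum_items": {
    "arousal": {"spontaneous": 0, "to_verbal": 1, "to_pain": 2, "none": 3},
    "awareness": {"correct_response": 0, "confused_response": 1,
                  "nonreflex_movements": 2, "none": 3},
    "pupillary_reflex": {"bilateral_sensitive": 0,
                         "unilateral_slow_absent": 2,
                         "bilateral_slow_absent": 3},
    "corneal_reflex": {"bilateral_sensitive": 0,
                       "unilateral_slow_absent": 2,
                       "bilateral_slow_absent": 3},
    "verbal": {"accurate": 0, "confused_inappropriate": 1,
               "incomprehensible_none": 2},
    "swallow": {"wst_I_II": 0, "wst_III_IV_or_unable": 1}
  },
  "composite_items": {
    "motor": {
      "strength_test": [
        {"worst_grade_min": 4, "worst_grade_max": 5, "points": 0},
        {"worst_grade_min": 2, "worst_grade_max": 3, "points": 1},
        {"worst_grade_min": 0, "worst_grade_max": 1, "unilateral": true,
         "points": 2},
        {"worst_grade_min": 0, "worst_grade_max": 1, "unilateral": false,
         "points": 3}],
      "pain_response": {"obeys": 0, "localizes_withdraws": 1,
                        "flexes_extends": 2, "none": 3}
    },
    "respiration": [
      {"intubated": false, "rate_min": 12, "rate_max": 24, "points": 0},
      {"intubated": false, "rate_min": null, "rate_max": 11, "points": 1},
      {"intubated": false, "rate_min": 25, "rate_max": null, "points": 1},
      {"intubated": true, "vent_interaction": "above_rate", "points": 2},
      {"intubated": true, "vent_interaction": "at_rate_or_apnea", "points": 3}
    ],
    "verbal_intubated_override": {"points": 2}
  }
}
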