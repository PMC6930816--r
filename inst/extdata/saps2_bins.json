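{
  "version": "1.0",
  "score": "saps2",
  "max_total": 163,
  "numeric_items": {
    "age": {"digits": 0, "bins": [
      {"lo": null, "hi": 39, "points": 0},
      {"lo": 40, "hi": 59, "points": 7},
      {"lo": 60, "hi": 69, "points": 12},
      {"lo": 70, "hi": 74, "points": 15},
      {"lo": 75, "hi": 79, "points": 16},
      {"lo": 80, "hi": null, "points": 18}]},
    "heart_rate": {"digits": 0, "bins": [
      {"lo": null, "hi": 39, "points": 11},
      {"lo": 40, "hi": 69, "points": 2},
      {"lo": 70, "hi": 119, "points": 0},
      {"lo": 120, "hi": 159, "points": 4},
      {"lo": 160, "hi": null, "points": 7}]},
    "sbp": {"digits": 0, "bins": [
      {"lo": null, "hi": 69, "points": 13},
      {"lo": 70, "hi": 99, "points": 5},
      {"lo": 100, "hi": 199, "points": 0},
      {"lo": 200, "hi": null, "points": 2}]},
    "temperature_core": {"digits": 1, "bins": [
      {"lo": null, "hi": 38.9, "points": 0},
      {"lo": 39, "hi": null, "points": 3}]},
    "pf_ratio": {"digits": 0, "bins": [
      {"lo": null, "hi": 99, "points": 11},
      {"lo": 100, "hi": 199, "points": 9},
      {"lo": 200, "hi": null, "points": 6}]},
    "urine_output_l": {"digits": 3, "bins": [
      {"lo": null, "hi": 0.499, "points": 11},
      {"lo": 0.5, "hi": 0.999, "points": 4},
      {"lo": 1, "hi": null, "points": 0}]},
    "urea": {"digits": 1, "bins": [
      {"lo": null, "hi": 9.9, "points": 0},
      {"lo": 10, "hi": 29.9, "points": 6},
      {"lo": 30, "hi": null, "points": 10}]},
    "wbc": {"digits": 1, "bins": [
      {"lo": null, "hi": 0.9, "points": 12},
      {"lo": 1, "hi": 19.9, "points": 0},
      {"lo": 20, "hi": null, "points": 3}]},
    "potassium": {"digits": 1, "bins": [
      {"lo": null, "hi": 2.9, "points": 3},
      {"lo": 3, "hi": 4.9, "points": 0},
      {"lo": 5, "hi": null, "points": 3}]},
    "sodium": {"digits": 0, "bins": [
      {"lo": null, "hi": 124, "points": 5},
      {"lo": 125, "hi": 144, "points": 0},
      {"lo": 145, "hi": null, "points": 1}]},
    "hco3": {"digits": 0, "bins": [
      {"lo": null, "hi": 14, "points": 6},
      {"lo": 15, "hi": 19, "points": 3},
      {"lo": 20, "hi": null, "points": 0}]},
    "bilirubin": {"digits": 1, "bins": [
      {"lo": null, "hi": 68.3, "points": 0},
      {"lo": 68.4, "hi": 102.5, "points": 4},
      {"lo": 102.6, "hi": null, "points": 9}]},
    "gcs": {"digits": 0, "bins": [
      {"lo": null, "hi": 5, "points": 26},
      {"lo": 6, "hi": 8, "points": 13},
      {"lo": 9, "hi": 10, "points": 7},
      {"lo": 11, "hi": 13, "points": 5},
      {"lo": 14, "hi": 15, "points": 0}]}
  },
  "enum_items": {
    "saps_chronic": {"none": 0, "metastatic_cancer": 9,
                     "hematologic_malignancy": 10, "aids": 17},
    "admission_type": {"scheduled_surgical": 0, "medical": 6,
                       "unscheduled_surgical": 8}
  },
  "rules": {
    "oxygenation": "pao2/fio2 bins apply only to ventilated patients; others score 0"
  }
}
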