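{
  "version": "1.0",
  "score": "apache2",
  "max_total": 71,
  "numeric_items": {
    "temperature_core": {"digits": 1, "bins": [
      {"lo": null, "hi": 29.9, "points": 4},
      {"lo": 30, "hi": 31.9, "points": 3},
      {"lo": 32, "hi": 33.9, "points": 2},
      {"lo": 34, "hi": 35.9, "points": 1},
      {"lo": 36, "hi": 38.4, "points": 0},
      {"lo": 38.5, "hi": 38.9, "points": 1},
      {"lo": 39, "hi": 40.9, "points": 3},
      {"lo": 41, "hi": null, "points": 4}]},
    "map": {"digits": 0, "bins": [
      {"lo": null, "hi": 49, "points": 4},
      {"lo": 50, "hi": 69, "points": 2},
      {"lo": 70, "hi": 109, "points": 0},
      {"lo": 110, "hi": 129, "points": 2},
      {"lo": 130, "hi": 159, "points": 3},
      {"lo": 160, "hi": null, "points": 4}]},
    "heart_rate": {"digits": 0, "bins": [
      {"lo": null, "hi": 39, "points": 4},
      {"lo": 40, "hi": 54, "points": 3},
      {"lo": 55, "hi": 69, "points": 2},
      {"lo": 70, "hi": 109, "points": 0},
      {"lo": 110, "hi": 139, "points": 2},
      {"lo": 140, "hi": 179, "points": 3},
      {"lo": 180, "hi": null, "points": 4}]},
    "resp_rate": {"digits": 0, "bins": [
      {"lo": null, "hi": 5, "points": 4},
      {"lo": 6, "hi": 9, "points": 2},
      {"lo": 10, "hi": 11, "points": 1},
      {"lo": 12, "hi": 24, "points": 0},
      {"lo": 25, "hi": 34, "points": 1},
      {"lo": 35, "hi": 49, "points": 3},
      {"lo": 50, "hi": null, "points": 4}]},
    "ph": {"digits": 2, "bins": [
      {"lo": null, "hi": 7.14, "points": 4},
      {"lo": 7.15, "hi": 7.24, "points": 3},
      {"lo": 7.25, "hi": 7.32, "points": 2},
      {"lo": 7.33, "hi": 7.49, "points": 0},
      {"lo": 7.5, "hi": 7.59, "points": 1},
      {"lo": 7.6, "hi": 7.69, "points": 3},
      {"lo": 7.7, "hi": null, "points": 4}]},
    "hco3": {"digits": 1, "bins": [
      {"lo": null, "hi": 14.9, "points": 4},
      {"lo": 15, "hi": 17.9, "points": 3},
      {"lo": 18, "hi": 21.9, "points": 2},
      {"lo": 22, "hi": 31.9, "points": 0},
      {"lo": 32, "hi": 40.9, "points": 1},
      {"lo": 41, "hi": 51.9, "points": 3},
      {"lo": 52, "hi": null, "points": 4}]},
    "sodium": {"digits": 0, "bins": [
      {"lo": null, "hi": 110, "points": 4},
      {"lo": 111, "hi": 119, "points": 3},
      {"lo": 120, "hi": 129, "points": 2},
      {"lo": 130, "hi": 149, "points": 0},
      {"lo": 150, "hi": 154, "points": 1},
      {"lo": 155, "hi": 159, "points": 2},
      {"lo": 160, "hi": 179, "points": 3},
      {"lo": 180, "hi": null, "points": 4}]},
    "potassium": {"digits": 1, "bins": [
      {"lo": null, "hi": 2.4, "points": 4},
      {"lo": 2.5, "hi": 2.9, "points": 2},
      {"lo": 3, "hi": 3.4, "points": 1},
      {"lo": 3.5, "hi": 5.4, "points": 0},
      {"lo": 5.5, "hi": 5.9, "points": 1},
      {"lo": 6, "hi": 6.9, "points": 3},
      {"lo": 7, "hi": null, "points": 4}]},
    "creatinine_mgdl": {"digits": 1, "bins": [
      {"lo": null, "hi": 0.5, "points": 2},
      {"lo": 0.6, "hi": 1.4, "points": 0},
      {"lo": 1.5, "hi": 1.9, "points": 2},
      {"lo": 2, "hi": 3.4, "points": 3},
      {"lo": 3.5, "hi": null, "points": 4}]},
    "hematocrit": {"digits": 1, "bins": [
      {"lo": null, "hi": 19.9, "points": 4},
      {"lo": 20, "hi": 29.9, "points": 2},
      {"lo": 30, "hi": 45.9, "points": 0},
      {"lo": 46, "hi": 49.9, "points": 1},
      {"lo": 50, "hi": 59.9, "points": 2},
      {"lo": 60, "hi": null, "points": 4}]},
    "wbc": {"digits": 1, "bins": [
      {"lo": null, "hi": 0.9, "points": 4},
      {"lo": 1, "hi": 2.9, "points": 2},
      {"lo": 3, "hi": 14.9, "points": 0},
      {"lo": 15, "hi": 19.9, "points": 1},
      {"lo": 20, "hi": 39.9, "points": 2},
      {"lo": 40, "hi": null, "points": 4}]},
    "aa_gradient": {"digits": 0, "bins": [
      {"lo": null, "hi": 199, "points": 0},
      {"lo": 200, "hi": 349, "points": 2},
      {"lo": 350, "hi": 499, "points": 3},
      {"lo": 500, "hi": null, "points": 4}]},
    "pao2": {"digits": 0, "bins": [
      {"lo": null, "hi": 54, "points": 4},
      {"lo": 55, "hi": 60, "points": 3},
      {"lo": 61, "hi": 70, "points": 1},
      {"lo": 71, "hi": null, "points": 0}]},
    "age": {"digits": 0, "bins": [
      {"lo": null, "hi": 44, "points": 0},
      {"lo": 45, "hi": 54, "points": 2},
      {"lo": 55, "hi": 64, "points": 3},
      {"lo": 65, "hi": 74, "points": 5},
      {"lo": 75, "hi": null, "points": 6}]}
  },
  "rules": {
    "oxygenation": "fio2 >= 0.5 uses aa_gradient bins; fio2 < 0.5 uses pao2 bins",
    "acid_base": "arterial ph preferred; serum hco3 bins when ph absent",
    "creatinine": "points doubled in acute renal failure",
    "gcs_item": "15 - (eye + verbal + motor)",
    "chronic_health": {"none": 0, "organ_insufficiency_scheduled_surgical": 2,
                       "organ_insufficiency_other": 5}
  }
}
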