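test_that("reference snapshots hit both ends of the scale", {
  normal <- score_incns(snapshot_all_normal())
  expect_identical(normal$total, 0L)
  expect_true(all(normal$items$points == 0L))

  worst <- score_incns(snapshot_worst_case())
  expect_identical(worst$total, 44L)
  expect_identical(worst$items$points, worst$items$max_points)
  expect_identical(
    worst$subtotals,
    c(inflammation = 4L, nutrition = 2L, consciousness = 6L,
      neurologic_function = 15L, systemic_condition = 17L))
})

test_that("scoresheet has 19 items in 5 categories with printed maxima", {
  reg <- incns_items()
  expect_identical(nrow(reg), 19L)
  expect_setequal(unique(reg$category),
                  c("inflammation", "nutrition", "consciousness",
                    "neurologic_function", "systemic_condition"))
  expect_identical(sum(reg$max_points), 44L)
  # per-row maxima: 1 for swallowing, 3 for the consciousness/neuro/age rows,
  # 2 elsewhere
  expect_identical(reg$max_points[reg$item == "swallow"], 1L)
  for (it in c("arousal", "awareness", "pupillary_reflex", "corneal_reflex",
               "motor", "respiration", "age"))
    expect_identical(reg$max_points[reg$item == it], 3L)
})

test_that("worked example matches the independent table-lookup oracle", {
  fields <- normal_fields(
    age = 70, wbc = 12, temperature_ax = 39, albumin = 30,
    arousal = "to_pain", awareness = "nonreflex_movements",
    pupillary_reflex = "unilateral_slow_absent",
    corneal_reflex = "bilateral_sensitive", verbal = "incomprehensible_none",
    motor_mode = "pain_response", motor_pain = "flexes_extends",
    swallow = "wst_III_IV_or_unable", intubated = TRUE,
    vent_interaction = "above_rate", heart_rate = 110, sbp = 150,
    glucose = 12, sodium = 155, potassium = 3, creatinine = 180,
    bilirubin = 40)
  oracle <- oracle_incns_points(fields)
  expect_identical(sum(oracle), 26L)
  res <- score_incns(do.call(patient_snapshot, fields))
  expect_identical(res$total, 26L)
  expect_identical(res$items$points[match(names(oracle), res$items$item)],
                   unname(oracle))
})

test_that("scorer agrees with the JSON oracle on random snapshots", {
  set.seed(42)
  for (i in 1:150) {
    fields <- random_snapshot_fields()
    res <- score_incns(do.call(patient_snapshot, fields))
    oracle <- oracle_incns_points(fields)
    expect_identical(res$items$points[match(names(oracle), res$items$item)],
                     unname(oracle),
                     info = paste("snapshot", i))
    expect_identical(res$total, sum(res$items$points))
    expect_identical(unname(res$total), as.integer(sum(oracle)))
  }
})

test_that("printed boundary cells score as printed", {
  cases <- list(
    list("wbc", 10.0, 0L), list("wbc", 10.1, 1L), list("wbc", 4.0, 0L),
    list("wbc", 3.9, 1L), list("wbc", 2.9, 1L), list("wbc", 2.8, 2L),
    list("wbc", 25.0, 1L), list("wbc", 25.1, 2L),
    list("temperature_ax", 36.0, 0L), list("temperature_ax", 35.9, 1L),
    list("temperature_ax", 38.4, 0L), list("temperature_ax", 38.5, 1L),
    list("temperature_ax", 40.0, 1L), list("temperature_ax", 40.1, 2L),
    list("albumin", 35.0, 0L), list("albumin", 34.9, 1L),
    list("albumin", 25.0, 1L), list("albumin", 24.9, 2L),
    list("age", 44, 0L), list("age", 45, 1L), list("age", 64, 1L),
    list("age", 65, 2L), list("age", 74, 2L), list("age", 75, 3L),
    list("heart_rate", 60, 0L), list("heart_rate", 59, 1L),
    list("heart_rate", 40, 1L), list("heart_rate", 39, 2L),
    list("heart_rate", 100, 0L), list("heart_rate", 101, 1L),
    list("heart_rate", 149, 1L), list("heart_rate", 150, 2L),
    list("sbp", 90, 0L), list("sbp", 89, 1L), list("sbp", 70, 1L),
    list("sbp", 69, 2L), list("sbp", 140, 0L), list("sbp", 141, 1L),
    list("sbp", 199, 1L), list("sbp", 200, 2L),
    list("glucose", 3.9, 0L), list("glucose", 3.8, 1L),
    list("glucose", 2.2, 1L), list("glucose", 2.1, 2L),
    list("glucose", 11.1, 0L), list("glucose", 11.2, 1L),
    list("glucose", 19.3, 1L), list("glucose", 19.4, 2L),
    list("sodium", 130, 0L), list("sodium", 129, 1L),
    list("sodium", 120, 1L), list("sodium", 119, 2L),
    list("sodium", 150, 0L), list("sodium", 151, 1L),
    list("sodium", 159, 1L), list("sodium", 160, 2L),
    list("potassium", 3.5, 0L), list("potassium", 3.4, 1L),
    list("potassium", 2.5, 1L), list("potassium", 2.4, 2L),
    list("potassium", 5.5, 0L), list("potassium", 5.6, 1L),
    list("potassium", 6.9, 1L), list("potassium", 7.0, 2L),
    list("creatinine", 44, 0L), list("creatinine", 43, 1L),
    list("creatinine", 40, 1L), list("creatinine", 132, 0L),
    list("creatinine", 133, 1L), list("creatinine", 171, 1L),
    list("creatinine", 172, 2L),
    list("bilirubin", 34.1, 0L), list("bilirubin", 34.2, 1L),
    list("bilirubin", 102.5, 1L), list("bilirubin", 102.6, 2L))
  for (cs in cases)
    expect_identical(score_item(cs[[1]], cs[[2]])$points, cs[[3]],
                     info = paste(cs[[1]], cs[[2]]))
  # enumerated rows
  expect_identical(score_item("pupillary_reflex", "bilateral_slow_absent")$points, 3L)
  expect_identical(score_item("pupillary_reflex", "unilateral_slow_absent")$points, 2L)
  expect_identical(score_item("corneal_reflex", "bilateral_sensitive")$points, 0L)
  expect_identical(score_item("swallow", "wst_III_IV_or_unable")$points, 1L)
  expect_identical(score_item("arousal", "to_pain")$points, 2L)
  expect_identical(score_item("awareness", "none")$points, 3L)
  expect_identical(score_item("verbal", "confused_inappropriate")$points, 1L)
})

test_that("inputs are rounded to the table's printed precision", {
  expect_identical(score_item("temperature_ax", 38.44)$points, 0L)
  expect_identical(score_item("temperature_ax", 38.46)$points, 1L)
  expect_identical(score_item("wbc", 10.04)$points, 0L)
  expect_identical(score_item("sodium", 150.4)$points, 0L)
  expect_identical(score_item("sodium", 150.6)$points, 1L)
})

test_that("binning is total and monotone away from the normal bin", {
  grids <- list(
    wbc = seq(0, 50, by = 0.1), temperature_ax = seq(30, 44, by = 0.1),
    albumin = seq(5, 60, by = 0.1), age = 0:110, heart_rate = 0:220,
    sbp = 0:260, glucose = seq(0, 35, by = 0.1), sodium = 95:190,
    potassium = seq(0, 10, by = 0.1), creatinine = 0:700,
    bilirubin = seq(0, 250, by = 0.1))
  for (nm in names(grids)) {
    g <- grids[[nm]]
    df <- stats::setNames(data.frame(g), nm)
    pts <- incns:::incns_points_matrix(df)[, nm]
    expect_false(anyNA(pts), info = nm)          # bin completeness
    expect_true(all(pts %in% 0:3), info = nm)
    z <- which(pts == 0L)
    expect_gt(length(z), 0)
    # moving away from the 0-point region never decreases points
    left <- pts[seq_len(min(z))]
    right <- pts[seq(max(z), length(pts))]
    expect_true(all(diff(left) <= 0), info = nm)
    expect_true(all(diff(right) >= 0), info = nm)
  }
})

test_that("motor item follows the worst-limb and pain rules", {
  expect_identical(score_motor(make_snapshot(motor_strength_worst = 4))$points, 0L)
  expect_identical(score_motor(make_snapshot(motor_strength_worst = 5))$points, 0L)
  expect_identical(score_motor(make_snapshot(motor_strength_worst = 2))$points, 1L)
  expect_identical(score_motor(make_snapshot(motor_strength_worst = 3))$points, 1L)
  expect_identical(score_motor(make_snapshot(
    motor_strength_worst = 1, motor_strength_unilateral_low = TRUE))$points, 2L)
  expect_identical(score_motor(make_snapshot(
    motor_strength_worst = 0, motor_strength_unilateral_low = FALSE))$points, 3L)
  expect_identical(score_motor(make_snapshot(
    motor_mode = "pain_response", motor_pain = "obeys"))$points, 0L)
  expect_identical(score_motor(make_snapshot(
    motor_mode = "pain_response", motor_pain = "localizes_withdraws"))$points, 1L)
  expect_identical(score_motor(make_snapshot(
    motor_mode = "pain_response", motor_pain = "flexes_extends"))$points, 2L)
  expect_identical(score_motor(make_snapshot(
    motor_mode = "pain_response", motor_pain = "none"))$points, 3L)
  expect_error(patient_snapshot(motor_mode = "strength_test",
                                motor_pain = "obeys"),
               "strength_test")
})

test_that("respiration item follows the four degrees", {
  expect_identical(score_respiration(make_snapshot(resp_rate = 18))$points, 0L)
  expect_identical(score_respiration(make_snapshot(resp_rate = 12))$points, 0L)
  expect_identical(score_respiration(make_snapshot(resp_rate = 24))$points, 0L)
  expect_identical(score_respiration(make_snapshot(resp_rate = 11))$points, 1L)
  expect_identical(score_respiration(make_snapshot(resp_rate = 25))$points, 1L)
  expect_identical(score_respiration(make_snapshot(
    intubated = TRUE, vent_interaction = "above_rate"))$points, 2L)
  expect_identical(score_respiration(make_snapshot(
    intubated = TRUE, vent_interaction = "at_rate_or_apnea"))$points, 3L)
  expect_error(patient_snapshot(intubated = TRUE, resp_rate = 20),
               "ventilator")
})

test_that("intubated patients score verbal as no response, with a warning", {
  snap <- make_snapshot(intubated = TRUE, verbal = "accurate",
                        vent_interaction = "above_rate")
  expect_warning(res <- score_incns(snap), "overridden")
  expect_identical(res$items$points[res$items$item == "verbal"], 2L)
  # consistent recording triggers no warning
  expect_silent(score_incns(make_snapshot(
    intubated = TRUE, verbal = "incomprehensible_none",
    vent_interaction = "above_rate")))
})

test_that("missing-data policy: hard error by default, flagged zeros on demand", {
  fields <- normal_fields()
  fields$wbc <- NULL
  fields$sodium <- NULL
  snap <- do.call(patient_snapshot, fields)
  expect_error(score_incns(snap), "wbc")
  expect_error(score_incns(snap), "sodium")
  res <- score_incns(snap, assume_normal = TRUE)
  expect_identical(res$items$points[res$items$item == "wbc"], 0L)
  expect_true(res$items$imputed[res$items$item == "wbc"])
  expect_identical(sum(res$items$imputed), 2L)
})

test_that("invalid raw values are rejected", {
  expect_error(patient_snapshot(wbc = -1), "negative")
  expect_error(patient_snapshot(arousal = "asleep"), "arousal")
  expect_error(patient_snapshot(motor_mode = "strength_test",
                                motor_strength_worst = 7), "MRC")
  expect_error(score_item("nonsense", 1), "unknown item")
  expect_error(score_item("motor", 2), "named fields")
})

test_that("scoring is pure: same snapshot, same result", {
  snap <- make_snapshot(wbc = 11, arousal = "to_verbal")
  expect_identical(score_incns(snap), score_incns(snap))
})

test_that("code tables match the bundled JSON transcription", {
  tb <- load_bin_table("incns")
  for (nm in names(tb$numeric_items)) {
    js <- incns:::json_bins_to_internal(tb$numeric_items[[nm]])
    code <- incns:::incns_numeric_items[[nm]]
    expect_identical(js$digits, code$digits, info = nm)
    expect_equal(js$lower, code$lower, info = nm)
    expect_identical(js$points, code$points, info = nm)
  }
  for (nm in names(tb$enum_items)) {
    js <- unlist(tb$enum_items[[nm]])
    code <- incns:::incns_enum_items[[nm]]$levels
    expect_identical(as.integer(js[names(code)]), unname(code), info = nm)
  }
  expect_identical(as.integer(tb$max_total), 44L)
})
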