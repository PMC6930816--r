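# Independent oracles, deliberately coded apart from the package internals:
# the scoresheet oracle interprets the declarative JSON transcription, the
# AUC oracle enumerates positive-negative pairs, the Youden oracle searches
# all thresholds exhaustively.

`%null%` <- function(x, y) if (is.null(x)) y else x

# JSON-driven INCNS scorer (per-item points + total) for fully observed
# snapshots represented as plain named lists
oracle_incns_points <- function(snap) {
  tb <- jsonlite::read_json(system.file("extdata", "incns_bins.json",
                                        package = "incns"))
  pts <- list()
  for (nm in names(tb$numeric_items)) {
    it <- tb$numeric_items[[nm]]
    v <- round(snap[[nm]], it$digits)
    for (b in it$bins) {
      lo <- b$lo %null% -Inf
      hi <- b$hi %null% Inf
      if (v >= lo - 1e-9 && v <= hi + 1e-9) { pts[[nm]] <- b$points; break }
    }
  }
  for (nm in names(tb$enum_items))
    pts[[nm]] <- tb$enum_items[[nm]][[snap[[nm]]]]
  if (isTRUE(snap$intubated))
    pts$verbal <- tb$composite_items$verbal_intubated_override$points
  if (snap$motor_mode == "strength_test") {
    g <- snap$motor_strength_worst
    for (r in tb$composite_items$motor$strength_test) {
      uni_ok <- is.null(r$unilateral) ||
        identical(r$unilateral, isTRUE(snap$motor_strength_unilateral_low))
      if (g >= r$worst_grade_min && g <= r$worst_grade_max && uni_ok) {
        pts$motor <- r$points
        break
      }
    }
  } else {
    pts$motor <- tb$composite_items$motor$pain_response[[snap$motor_pain]]
  }
  for (r in tb$composite_items$respiration) {
    if (!identical(r$intubated, isTRUE(snap$intubated))) next
    if (isTRUE(snap$intubated)) {
      if (identical(r$vent_interaction, snap$vent_interaction)) {
        pts$respiration <- r$points
        break
      }
    } else {
      lo <- r$rate_min %null% -Inf
      hi <- r$rate_max %null% Inf
      if (snap$resp_rate >= lo && snap$resp_rate <= hi) {
        pts$respiration <- r$points
        break
      }
    }
  }
  vapply(pts, as.integer, integer(1))
}

# AUC by explicit enumeration of positive-negative pairs (wins + half-ties)
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Youden maximizer by exhaustive search over all candidate cutoffs
# (rule: score >= cutoff predicts positive; smallest cutoff on ties)
oracle_youden <- function(scores, labels) {
  labels <- as.logical(labels)
  m <- sum(labels); n <- sum(!labels)
  cand <- sort(unique(c(scores, Inf)))
  # exact integer form of sens + spec - 1 = tp/m - fp/n: tp*n - fp*m
  jint <- vapply(cand, function(t) {
    pred <- scores >= t
    sum(pred & labels) * n - sum(pred & !labels) * m
  }, numeric(1))
  best <- which(jint == max(jint))
  list(cutoff = min(cand[best]), youden = max(jint) / (m * n))
}

# random scores/labels fixture with ties, both classes guaranteed
random_fixture <- function(n, max_score = 20) {
  repeat {
    s <- sample(0:max_score, n, replace = TRUE)
    l <- runif(n) < 0.5
    if (any(l) && !all(l)) return(list(scores = s, labels = l))
  }
}

# an all-normal snapshot as a plain list, with overrides
normal_fields <- function(...) {
  base <- list(
    wbc = 7, temperature_ax = 36.8, albumin = 40, arousal = "spontaneous",
    awareness = "correct_response", pupillary_reflex = "bilateral_sensitive",
    corneal_reflex = "bilateral_sensitive", verbal = "accurate",
    motor_mode = "strength_test", motor_strength_worst = 5,
    motor_strength_unilateral_low = FALSE, swallow = "wst_I_II",
    intubated = FALSE, resp_rate = 16, age = 30, heart_rate = 75, sbp = 120,
    glucose = 5.5, sodium = 140, potassium = 4, creatinine = 80,
    bilirubin = 10)
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  # keep structural invariants when switching assessment paths
  if (identical(base$motor_mode, "pain_response")) {
    base$motor_strength_worst <- NULL
    base$motor_strength_unilateral_low <- NULL
    if (is.null(base$motor_pain)) base$motor_pain <- "obeys"
  }
  if (isTRUE(base$intubated)) {
    base$resp_rate <- NULL
    if (is.null(base$vent_interaction)) base$vent_interaction <- "above_rate"
  }
  base
}

make_snapshot <- function(...) do.call(patient_snapshot, normal_fields(...))

# a random fully observed snapshot (valid by construction)
random_snapshot_fields <- function() {
  strength <- runif(1) < 0.5
  intub <- runif(1) < 0.3
  f <- list(
    wbc = round(runif(1, 0, 50), 1),
    temperature_ax = round(runif(1, 32, 43), 1),
    albumin = round(runif(1, 10, 55), 1),
    arousal = sample(c("spontaneous", "to_verbal", "to_pain", "none"), 1),
    awareness = sample(c("correct_response", "confused_response",
                         "nonreflex_movements", "none"), 1),
    pupillary_reflex = sample(c("bilateral_sensitive",
                                "unilateral_slow_absent",
                                "bilateral_slow_absent"), 1),
    corneal_reflex = sample(c("bilateral_sensitive", "unilateral_slow_absent",
                              "bilateral_slow_absent"), 1),
    verbal = sample(c("accurate", "confused_inappropriate",
                      "incomprehensible_none"), 1),
    swallow = sample(c("wst_I_II", "wst_III_IV_or_unable"), 1),
    age = sample(16:95, 1),
    heart_rate = sample(20:200, 1),
    sbp = sample(40:250, 1),
    glucose = round(runif(1, 1, 30), 1),
    sodium = sample(105:180, 1),
    potassium = round(runif(1, 1.5, 9), 1),
    creatinine = sample(15:600, 1),
    bilirubin = round(runif(1, 1, 200), 1),
    motor_mode = if (strength) "strength_test" else "pain_response",
    intubated = intub)
  if (strength) {
    f$motor_strength_worst <- sample(0:5, 1)
    f$motor_strength_unilateral_low <- runif(1) < 0.5
  } else {
    f$motor_pain <- sample(c("obeys", "localizes_withdraws", "flexes_extends",
                             "none"), 1)
  }
  if (intub) {
    f$vent_interaction <- sample(c("above_rate", "at_rate_or_apnea"), 1)
    f$verbal <- "incomprehensible_none"
  } else {
    f$resp_rate <- sample(4:50, 1)
  }
  f
}
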