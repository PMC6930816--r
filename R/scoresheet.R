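# Vectorized scoring core. `df` holds one row per snapshot and one column per
# snapshot field (missing columns are treated as all-NA). Returns an integer
# matrix of item points (NA where the item cannot be scored) -- policy
# (error vs assume-normal) is applied by the callers.
incns_points_matrix <- function(df, warn_verbal_override = TRUE) {
  n <- nrow(df)
  col <- function(nm) if (nm %in% names(df)) df[[nm]] else rep(NA, n)
  pts <- matrix(NA_integer_, nrow = n, ncol = nrow(incns_item_registry),
                dimnames = list(NULL, incns_item_registry$item))

  for (nm in names(incns_numeric_items)) {
    row <- incns_numeric_items[[nm]]
    pts[, nm] <- bin_points(as.numeric(col(nm)), row$lower, row$points,
                            row$digits)
  }
  for (nm in setdiff(names(incns_enum_items), "verbal")) {
    pts[, nm] <- enum_points(as.character(col(nm)),
                             incns_enum_items[[nm]]$levels)
  }

  # verbal: intubated patients score "incomprehensible speech/none" (2),
  # overriding any recorded verbal value
  verbal <- as.character(col("verbal"))
  intub <- as.logical(col("intubated"))
  vp <- enum_points(verbal, incns_enum_items$verbal$levels)
  forced <- !is.na(intub) & intub
  if (warn_verbal_override &&
      any(forced & !is.na(verbal) & verbal != "incomprehensible_none"))
    warning("intubated patient(s): verbal response overridden to ",
            "'incomprehensible speech/none' (2 points)", call. = FALSE)
  vp[forced] <- 2L
  pts[, "verbal"] <- vp

  # motor: worst-limb strength grade or pain-response category
  mode <- as.character(col("motor_mode"))
  g <- as.numeric(col("motor_strength_worst"))
  uni <- as.logical(col("motor_strength_unilateral_low"))
  pain <- as.character(col("motor_pain"))
  mp <- rep(NA_integer_, n)
  st <- !is.na(mode) & mode == "strength_test" & !is.na(g)
  mp[st & g >= 4] <- 0L
  mp[st & g >= 2 & g <= 3] <- 1L
  low <- st & g <= 1
  mp[low & !is.na(uni) & uni] <- 2L
  mp[low & !is.na(uni) & !uni] <- 3L
  pr <- !is.na(mode) & mode == "pain_response"
  mp[pr] <- enum_points(pain[pr], motor_pain_levels)
  pts[, "motor"] <- mp

  # respiration: four degrees
  rate <- as.numeric(col("resp_rate"))
  vi <- as.character(col("vent_interaction"))
  rp <- rep(NA_integer_, n)
  ni <- !is.na(intub) & !intub & !is.na(rate)
  rate_r <- round(rate)
  rp[ni & rate_r >= 12 & rate_r <= 24] <- 0L
  rp[ni & (rate_r <= 11 | rate_r >= 25)] <- 1L
  iv <- !is.na(intub) & intub
  rp[iv] <- enum_points(vi[iv], vent_interaction_levels)
  pts[, "respiration"] <- rp

  pts
}

# Raw fields to report when an item is missing (conditionally required
# companions resolved against the row).
missing_fields_for_item <- function(item, row) {
  if (item == "motor") {
    if (!has_value(row$motor_mode)) return("motor_mode")
    if (row$motor_mode == "strength_test") {
      out <- character(0)
      if (!has_value(row$motor_strength_worst)) out <- c(out, "motor_strength_worst")
      if (!has_value(row$motor_strength_unilateral_low) &&
          has_value(row$motor_strength_worst) && row$motor_strength_worst <= 1)
        out <- c(out, "motor_strength_unilateral_low")
      return(out)
    }
    return("motor_pain")
  }
  if (item == "respiration") {
    if (!has_value(row$intubated)) return("intubated")
    if (isTRUE(row$intubated)) return("vent_interaction") else return("resp_rate")
  }
  if (item == "verbal") return("verbal")
  item
}

#' Score the INCNS scoresheet for one patient snapshot
#'
#' Applies the 19-item scoresheet to a [patient_snapshot()]: each item is
#' looked up in its point bins (numeric rows at their printed precision) and
#' summed into five category subtotals and a 0-44 total.
#'
#' Missing-data policy: by default any item that cannot be scored raises an
#' error naming the missing raw fields. With `assume_normal = TRUE`, missing
#' items score 0 points and are flagged in the `imputed` column of the result,
#' so downstream reports can audit the imputation.
#'
#' @param snapshot a [patient_snapshot()] (or a named list of fields).
#' @param assume_normal score missing items as 0 and flag them, instead of
#'   erroring.
#' @return An `incns_result`: list with `total` (integer, 0-44), `subtotals`
#'   (named integer vector over the five categories) and `items` (data.frame
#'   of per-item points with an `imputed` flag).
#' @seealso [score_item()], [score_motor()], [score_respiration()]
#' @export
score_incns <- function(snapshot, assume_normal = FALSE) {
  if (!inherits(snapshot, "patient_snapshot")) {
    if (!is.list(snapshot))
      stop("snapshot must be a patient_snapshot or a named list", call. = FALSE)
    snapshot <- do.call(patient_snapshot, snapshot[!vapply(snapshot, function(v)
      length(v) != 1L || is.na(v), logical(1))])
  }
  df <- snapshot_to_df(snapshot)
  pts <- incns_points_matrix(df)[1L, ]
  imputed <- is.na(pts)
  if (any(imputed) && !assume_normal) {
    miss <- unlist(lapply(names(pts)[imputed], missing_fields_for_item,
                          row = snapshot))
    stop_missing(unique(miss), "INCNS scoring")
  }
  pts[imputed] <- 0L
  items <- data.frame(item = incns_item_registry$item,
                      category = incns_item_registry$category,
                      points = unname(pts),
                      max_points = incns_item_registry$max_points,
                      imputed = unname(imputed),
                      stringsAsFactors = FALSE)
  subtotals <- vapply(incns_categories, function(cat)
    sum(items$points[items$category == cat]), integer(1))
  structure(list(total = sum(items$points), subtotals = subtotals,
                 items = items),
            class = "incns_result")
}

#' @export
print.incns_result <- function(x, ...) {
  cat("INCNS score:", x$total, "/ 44\n")
  for (nm in names(x$subtotals))
    cat("  ", format(nm, width = 20), x$subtotals[[nm]], "\n", sep = "")
  if (any(x$items$imputed))
    cat("  (", sum(x$items$imputed), " item(s) imputed as normal)\n", sep = "")
  invisible(x)
}

#' Score a single scoresheet item
#'
#' Looks up one item of the scoresheet. Single-field items take the raw value
#' as the second argument; the composite items (`motor`, `respiration`,
#' `verbal`) take their fields as named arguments (e.g.
#' `score_item("respiration", intubated = FALSE, resp_rate = 18)`).
#'
#' @param item one of the 19 item names in `incns_items()$item`.
#' @param value the raw value, for single-field items.
#' @param ... named snapshot fields, for composite items.
#' @return An `incns_item_score`: list with `item`, `points` and `category`.
#' @export
#' @examples
#' score_item("wbc", 10.1)$points      # 1
#' score_item("creatinine", 40)$points # 1 (low creatinine scores 1)
score_item <- function(item, value = NULL, ...) {
  reg <- incns_item_registry
  if (!item %in% reg$item) stop("unknown item: ", item, call. = FALSE)
  fields <- list(...)
  if (!is.null(value)) {
    if (item %in% c("motor", "respiration"))
      stop("composite item '", item, "' takes named fields, not a single value",
           call. = FALSE)
    fields[[item]] <- value
  }
  if (item == "verbal" && is.null(fields$intubated)) fields$intubated <- FALSE
  snap <- do.call(patient_snapshot, fields)
  pts <- incns_points_matrix(snapshot_to_df(snap), warn_verbal_override = FALSE)[1L, item]
  if (is.na(pts))
    stop_missing(missing_fields_for_item(item, snap), paste0("item '", item, "'"))
  structure(list(item = item, points = unname(pts),
                 category = reg$category[reg$item == item]),
            class = "incns_item_score")
}

#' @export
print.incns_item_score <- function(x, ...) {
  cat(sprintf("<%s> %d point(s) [%s]\n", x$item, x$points, x$category))
  invisible(x)
}

#' Score the motor-response item
#'
#' Either the muscle strength test or the pain-response test is performed per
#' patient. Strength path: worst-limb MRC grade >= 4 scores 0; grade 2-3
#' scores 1; grade <= 1 in one limb scores 2; grade <= 1 bilaterally scores 3.
#' Pain path: obeying 0, localizing/withdrawing 1, flexing/extending 2,
#' none 3.
#'
#' @param snapshot a [patient_snapshot()] with the motor fields populated.
#' @return An `incns_item_score`.
#' @export
score_motor <- function(snapshot) {
  pts <- incns_points_matrix(snapshot_to_df(snapshot), warn_verbal_override = FALSE)[1L, "motor"]
  if (is.na(pts))
    stop_missing(missing_fields_for_item("motor", snapshot), "item 'motor'")
  structure(list(item = "motor", points = unname(pts),
                 category = "neurologic_function"),
            class = "incns_item_score")
}

#' Score the respiration item
#'
#' Respiratory function in four degrees: not intubated with a rate of 12-24
#' scores 0; not intubated with a rate <= 11 or >= 25 scores 1; intubated and
#' breathing above the ventilator rate scores 2; breathing at the ventilator
#' rate or apnea scores 3.
#'
#' @param snapshot a [patient_snapshot()] with the respiration fields
#'   populated.
#' @return An `incns_item_score`.
#' @export
score_respiration <- function(snapshot) {
  pts <- incns_points_matrix(snapshot_to_df(snapshot), warn_verbal_override = FALSE)[1L, "respiration"]
  if (is.na(pts))
    stop_missing(missing_fields_for_item("respiration", snapshot),
                 "item 'respiration'")
  structure(list(item = "respiration", points = unname(pts),
                 category = "neurologic_function"),
            class = "incns_item_score")
}

#' Reference snapshots: all-normal and worst-possible
#'
#' `snapshot_all_normal()` returns a snapshot with every variable in a 0-point
#' bin (total 0). `snapshot_worst_case()` returns a snapshot with every
#' variable in its maximum bin; its total is the maximum attainable INCNS
#' score (44).
#'
#' @return A [patient_snapshot()].
#' @export
snapshot_all_normal <- function() {
  patient_snapshot(
    wbc = 7, temperature_ax = 36.8, albumin = 40, arousal = "spontaneous",
    awareness = "correct_response", pupillary_reflex = "bilateral_sensitive",
    corneal_reflex = "bilateral_sensitive", verbal = "accurate",
    motor_mode = "strength_test", motor_strength_worst = 5,
    motor_strength_unilateral_low = FALSE, swallow = "wst_I_II",
    intubated = FALSE, resp_rate = 16, age = 30, heart_rate = 75, sbp = 120,
    glucose = 5.5, sodium = 140, potassium = 4, creatinine = 80,
    bilirubin = 10)
}

#' @rdname snapshot_all_normal
#' @export
snapshot_worst_case <- function() {
  patient_snapshot(
    wbc = 30, temperature_ax = 41, albumin = 18, arousal = "none",
    awareness = "none", pupillary_reflex = "bilateral_slow_absent",
    corneal_reflex = "bilateral_slow_absent", verbal = "incomprehensible_none",
    motor_mode = "pain_response", motor_pain = "none",
    swallow = "wst_III_IV_or_unable", intubated = TRUE,
    vent_interaction = "at_rate_or_apnea", age = 90, heart_rate = 180,
    sbp = 230, glucose = 25, sodium = 170, potassium = 8, creatinine = 400,
    bilirubin = 150)
}
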