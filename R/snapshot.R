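incns_snapshot_fields <- c(
  "wbc", "temperature_ax", "albumin", "arousal", "awareness",
  "pupillary_reflex", "corneal_reflex", "verbal", "motor_mode",
  "motor_strength_worst", "motor_strength_unilateral_low", "motor_pain",
  "swallow", "intubated", "resp_rate", "vent_interaction", "age",
  "heart_rate", "sbp", "glucose", "sodium", "potassium", "creatinine",
  "bilirubin")

snapshot_enum_values <- list(
  arousal = c("spontaneous", "to_verbal", "to_pain", "none"),
  awareness = c("correct_response", "confused_response",
                "nonreflex_movements", "none"),
  pupillary_reflex = c("bilateral_sensitive", "unilateral_slow_absent",
                       "bilateral_slow_absent"),
  corneal_reflex = c("bilateral_sensitive", "unilateral_slow_absent",
                     "bilateral_slow_absent"),
  verbal = c("accurate", "confused_inappropriate", "incomprehensible_none"),
  motor_mode = c("strength_test", "pain_response"),
  motor_pain = c("obeys", "localizes_withdraws", "flexes_extends", "none"),
  swallow = c("wst_I_II", "wst_III_IV_or_unable"),
  vent_interaction = c("above_rate", "at_rate_or_apnea"))

# Numeric snapshot fields; all must be non-negative and finite when present.
snapshot_numeric_fields <- c("wbc", "temperature_ax", "albumin",
                             "motor_strength_worst", "resp_rate", "age",
                             "heart_rate", "sbp", "glucose", "sodium",
                             "potassium", "creatinine", "bilirubin")

#' Construct a patient snapshot
#'
#' A snapshot holds one time point's raw values for the 19 scoresheet
#' variables. Composite items are represented minimally: motor function as the
#' worst-limb MRC grade plus a flag for whether only one limb is at the low
#' grade (strength path) or a pain-response category (pain path), and
#' respiration as an intubation flag plus either a respiratory rate or the
#' patient-ventilator interaction.
#'
#' Fields may be omitted (left `NA`); the missing-data policy is applied at
#' scoring time, not at construction. Provided fields are validated:
#' enumerated fields against their vocabulary, numeric fields for
#' finiteness and non-negativity, and the structural invariants that exactly
#' one motor assessment is populated (matching `motor_mode`) and exactly one
#' respiration companion is populated (matching `intubated`).
#'
#' @param ... named snapshot fields (see `incns_snapshot_fields`).
#' @return An object of class `patient_snapshot` (a named list with one entry
#'   per snapshot field, `NA` where not provided).
#' @export
#' @examples
#' s <- patient_snapshot(age = 30, wbc = 7, temperature_ax = 36.8,
#'   albumin = 40, arousal = "spontaneous", awareness = "correct_response",
#'   pupillary_reflex = "bilateral_sensitive",
#'   corneal_reflex = "bilateral_sensitive", verbal = "accurate",
#'   motor_mode = "strength_test", motor_strength_worst = 5,
#'   swallow = "wst_I_II", intubated = FALSE, resp_rate = 16,
#'   heart_rate = 75, sbp = 120, glucose = 5.5, sodium = 140,
#'   potassium = 4, creatinine = 80, bilirubin = 10)
#' score_incns(s)$total # 0
patient_snapshot <- function(...) {
  given <- list(...)
  unknown <- setdiff(names(given), incns_snapshot_fields)
  if (length(unknown) > 0L ||
      (length(given) > 0L && (is.null(names(given)) || any(names(given) == ""))))
    stop("unknown or unnamed snapshot field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  snap <- stats::setNames(vector("list", length(incns_snapshot_fields)),
                          incns_snapshot_fields)
  snap[] <- NA
  for (nm in names(given)) if (!is.null(given[[nm]])) snap[[nm]] <- given[[nm]]
  validate_patient_snapshot(snap)
  structure(snap, class = "patient_snapshot")
}

has_value <- function(x) !is.null(x) && length(x) == 1L && !is.na(x)

validate_patient_snapshot <- function(snap) {
  for (nm in names(snapshot_enum_values)) {
    if (has_value(snap[[nm]]))
      assert_enum(snap[[nm]], snapshot_enum_values[[nm]], nm)
  }
  for (nm in snapshot_numeric_fields) {
    v <- snap[[nm]]
    if (has_value(v)) {
      if (!is_scalar_number(v))
        stop(sprintf("field '%s' must be a finite number", nm), call. = FALSE)
      if (v < 0)
        stop(sprintf("field '%s' is negative (%s): out of physiologic range",
                     nm, format(v)), call. = FALSE)
    }
  }
  if (has_value(snap$motor_strength_worst)) {
    g <- snap$motor_strength_worst
    if (g != round(g) || g > 5)
      stop("motor_strength_worst must be an integer MRC grade 0-5",
           call. = FALSE)
  }
  if (has_value(snap$intubated) && !is.logical(snap$intubated))
    stop("intubated must be logical", call. = FALSE)
  if (has_value(snap$motor_strength_unilateral_low) &&
      !is.logical(snap$motor_strength_unilateral_low))
    stop("motor_strength_unilateral_low must be logical", call. = FALSE)

  # structural invariants (only checked once the governing field is known)
  if (has_value(snap$motor_mode)) {
    st <- has_value(snap$motor_strength_worst)
    pn <- has_value(snap$motor_pain)
    if (snap$motor_mode == "strength_test" && pn)
      stop("motor_mode is strength_test but motor_pain is populated",
           call. = FALSE)
    if (snap$motor_mode == "pain_response" && st)
      stop("motor_mode is pain_response but motor_strength_worst is populated",
           call. = FALSE)
  } else if (has_value(snap$motor_strength_worst) && has_value(snap$motor_pain)) {
    stop("both motor assessments populated; exactly one is performed",
         call. = FALSE)
  }
  if (has_value(snap$intubated)) {
    if (isTRUE(snap$intubated) && has_value(snap$resp_rate))
      stop("intubated patients are scored by ventilator interaction, not rate",
           call. = FALSE)
    if (isFALSE(snap$intubated) && has_value(snap$vent_interaction))
      stop("vent_interaction populated for a non-intubated patient",
           call. = FALSE)
  }
  invisible(snap)
}

#' @export
print.patient_snapshot <- function(x, ...) {
  present <- x[!vapply(x, function(v) length(v) != 1L || is.na(v), logical(1))]
  cat("<patient_snapshot> ", length(present), " of ",
      length(incns_snapshot_fields), " fields present\n", sep = "")
  for (nm in names(present))
    cat("  ", format(nm, width = 28), format(present[[nm]]), "\n", sep = "")
  invisible(x)
}

# One-row data.frame view of a snapshot (missing -> NA), used by the
# vectorized scoring core.
snapshot_to_df <- function(snap) {
  vals <- lapply(incns_snapshot_fields, function(nm) {
    v <- snap[[nm]]
    if (is.null(v) || length(v) != 1L) NA else v
  })
  names(vals) <- incns_snapshot_fields
  as.data.frame(vals, stringsAsFactors = FALSE)
}
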